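#' @title Short-time Fourier analysis and synthesis
#' @name timefreq
#' @description STFT with a 50% overlapped 1-second periodic Hamming
#'   window — the convention shared by the frequency-domain separation
#'   methods — and the weighted overlap-add inverse with squared-window
#'   normalisation, which reconstructs fully covered samples exactly.
NULL

# periodic Hamming window of length L
hamming_periodic <- function(L) 0.54 - 0.46 * cos(2 * pi * (0:(L - 1L)) / L)

#' Short-time Fourier transform of a multichannel signal
#'
#' Frames start at sample 1 with hop `L/2` where `L = round(fs)` (a 1-s
#' window); trailing samples that do not fill a frame are dropped. Spectra
#' are one-sided: `I = L/2 + 1` bins at frequencies `(0:(L/2)) * fs / L`.
#'
#' @param x a [recording()] or a channels x samples numeric matrix.
#' @param fs sampling rate in Hz (taken from the recording if omitted).
#' @param window_sec window length in seconds (default 1).
#' @return An object of class `spectrogram`: complex array `tensor` of
#'   dimension channels x I x J, plus `fs`, `L`, `H`, `window`.
#' @examples
#' rec <- recording(matrix(rnorm(300), 3), fs = 100)
#' # too short for a 1-s window would be an error; 3 s gives J = 5 frames
#' sp <- stft(rec)
#' dim(sp$tensor)
#' @export
stft <- function(x, fs = NULL, window_sec = 1) {
  if (inherits(x, "recording")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$data
  }
  if (is.null(fs)) stop("length error: fs required for matrix input",
                        call. = FALSE)
  x <- rbind(x)  # ensure matrix for single-channel input
  P <- nrow(x); N <- ncol(x)
  L <- as.integer(round(fs * window_sec))
  if (L %% 2L == 1L) L <- L + 1L
  H <- L %/% 2L
  if (N < L)
    stop("length error: need at least ", L, " samples (one window), got ",
         N, call. = FALSE)
  J <- 1L + (N - L) %/% H
  I <- L %/% 2L + 1L
  w <- hamming_periodic(L)
  tens <- array(0 + 0i, c(P, I, J))
  for (p in seq_len(P)) {
    for (j in seq_len(J)) {
      seg <- x[p, ((j - 1L) * H + 1L):((j - 1L) * H + L)] * w
      tens[p, , j] <- stats::fft(seg)[1:I]
    }
  }
  structure(list(tensor = tens, fs = fs, L = L, H = H,
                 window = "hamming-periodic"),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<spectrogram> ", d[1L], " series x ", d[2L], " bins x ", d[3L],
      " frames (L=", x$L, ", H=", x$H, ", fs=", x$fs, ")\n", sep = "")
  invisible(x)
}

#' Bin centre frequencies of a spectrogram
#' @param spec a `spectrogram`.
#' @return numeric vector of length I, in Hz.
#' @export
stft_frequencies <- function(spec) {
  (0:(spec$L %/% 2L)) * spec$fs / spec$L
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add: each frame's one-sided spectrum is completed by
#' conjugate symmetry, inverse transformed, windowed again, summed, and
#' divided by the accumulated squared window (floored at 1e-12). Samples
#' covered by at least one full window reconstruct the analysed signal to
#' machine precision; the synthesis is linear in the spectrogram.
#'
#' @param spec a `spectrogram`.
#' @param out_length number of samples to return (must not exceed the
#'   synthesis support `L + (J-1)*H`).
#' @return channels x `out_length` numeric matrix.
#' @export
istft <- function(spec, out_length = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  d <- dim(spec$tensor)
  P <- d[1L]; I <- d[2L]; J <- d[3L]
  L <- spec$L; H <- spec$H
  support <- L + (J - 1L) * H
  if (is.null(out_length)) out_length <- support
  if (out_length > support)
    stop("synthesis error: requested ", out_length,
         " samples but synthesis support is ", support, call. = FALSE)
  w <- hamming_periodic(L)
  out <- matrix(0, P, support)
  den <- numeric(support)
  for (j in seq_len(J)) {
    idx <- ((j - 1L) * H + 1L):((j - 1L) * H + L)
    den[idx] <- den[idx] + w^2
  }
  den <- pmax(den, 1e-12)
  for (p in seq_len(P)) {
    acc <- numeric(support)
    for (j in seq_len(J)) {
      half <- spec$tensor[p, , j]
      full <- c(half, Conj(half[seq.int(I - 1L, 2L)]))
      frame <- Re(stats::fft(full, inverse = TRUE)) / L
      idx <- ((j - 1L) * H + 1L):((j - 1L) * H + L)
      acc[idx] <- acc[idx] + frame * w
    }
    out[p, ] <- acc / den
  }
  out[, seq_len(out_length), drop = FALSE]
}

# STFT of every epoch independently (no frames across epoch boundaries),
# frames concatenated along J. Returns the spectrogram plus frames-per-epoch.
epochs_to_spectrogram <- function(eps, window_sec = 1) {
  stopifnot(inherits(eps, "epoch_set"))
  d <- dim(eps$epochs)
  sp1 <- stft(eps$epochs[1L, , , drop = TRUE], fs = eps$fs,
              window_sec = window_sec)
  Je <- dim(sp1$tensor)[3L]
  tens <- array(0 + 0i, c(d[2L], dim(sp1$tensor)[2L], Je * d[1L]))
  tens[, , 1:Je] <- sp1$tensor
  if (d[1L] > 1L) for (t in 2:d[1L]) {
    spt <- stft(eps$epochs[t, , , drop = TRUE], fs = eps$fs,
                window_sec = window_sec)
    tens[, , ((t - 1L) * Je + 1L):(t * Je)] <- spt$tensor
  }
  sp <- structure(list(tensor = tens, fs = sp1$fs, L = sp1$L, H = sp1$H,
                       window = sp1$window), class = "spectrogram")
  list(spec = sp, frames_per_epoch = Je, n_epochs = d[1L],
       epoch_length = d[3L])
}
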