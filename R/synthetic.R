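#' @title Ground-truthed synthetic EEG
#' @name synthetic
#' @description Generates artifact-contaminated multichannel EEG as a
#'   linear instantaneous mixture `x(n) = A s(n) + d(n)`: oscillatory
#'   neuronal sources, steady-state visually evoked responses, stereotyped
#'   eyeblink pulse trains (about 20 per minute), broadband muscle bursts
#'   and low-rank broadband test sources, mixed through a
#'   distance-attenuated full-rank matrix plus white sensor noise. All
#'   stages of the separation/identification/reduction pipeline can be
#'   validated against the known sources and mixing.
NULL

source_kinds <- c("neuronal-osc", "ssvep", "eye-blink", "muscle-burst",
                  "lowrank")

ssvep_frequencies <- c(5.45, 6.67, 8.57, 12)

# smooth nonnegative envelope from linear interpolation of squared noise
smooth_envelope <- function(n, knots) {
  x <- stats::rnorm(knots)
  e <- stats::approx(seq_len(knots), x, n = n)$y^2
  e / max(e)
}

# block on/off gate with smoothed edges and a small floor
block_gate <- function(n, fs, duty = 0.5, block_sec = 2, floor = 0.05) {
  nb <- ceiling(n / (block_sec * fs))
  on <- stats::runif(nb) < duty
  g <- rep(on, each = block_sec * fs)[seq_len(n)]
  k <- max(5L, as.integer(fs / 4))
  gs <- stats::filter(g, rep(1 / k, k), sides = 2)
  gs <- as.numeric(gs)
  gs[is.na(gs)] <- g[is.na(gs)]
  pmax(gs, floor)
}

# broadband colored noise: white noise shaped in the frequency domain by a
# smooth random log-spectral envelope
colored_noise <- function(n, fs, roughness = 1.2, knots = 12) {
  f <- seq(0, fs / 2, length.out = knots)
  lg <- stats::rnorm(knots, 0, roughness)
  half <- exp(stats::approx(f, lg, xout = (0:(n %/% 2)) * fs / n)$y)
  spec <- stats::fft(stats::rnorm(n))
  env <- c(half, rev(half[2:(length(half) - 1L)]))
  Re(stats::fft(spec * env[seq_len(n)], inverse = TRUE)) / n
}

# band-limited white noise via zero-phase Butterworth filtering
band_noise <- function(n, fs, lo, hi, order = 4) {
  b <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  pad <- 4L * fs
  x <- as.numeric(signal::filtfilt(b, stats::rnorm(n + 2L * pad)))
  x[(pad + 1L):(pad + n)]
}

# smooth biphasic eyeblink template: a raised-cosine positive lobe
# followed by a shallower negative rebound, total width_sec long
blink_template <- function(fs, width_sec = 0.25) {
  n <- as.integer(round(width_sec * fs))
  n1 <- as.integer(round(0.6 * n))
  n2 <- n - n1
  main <- 0.5 * (1 - cos(2 * pi * seq_len(n1) / (n1 + 1L)))
  rebound <- -0.3 * 0.5 * (1 - cos(2 * pi * seq_len(n2) / (n2 + 1L)))
  c(main, rebound)
}

#' Generate synthetic source time series
#'
#' Available kinds and their parameters (all optional):
#' \describe{
#'   \item{`neuronal-osc`}{`freq` (Hz, default 10): narrowband oscillation
#'     around `freq`, amplitude-modulated by a smooth random envelope.}
#'   \item{`ssvep`}{`freq` (one of 5.45, 6.67, 8.57, 12 Hz, default 12):
#'     sinusoid plus half-amplitude second harmonic.}
#'   \item{`eye-blink`}{`interval_sec` (default 3), `width_sec` (default
#'     0.25), `amplitude` (default 8), `jitter_sec` (default 0): biphasic
#'     pulses every `interval_sec` — the resting blink rate of about 20
#'     per minute. With zero jitter a 60-s signal carries exactly 20
#'     events.}
#'   \item{`muscle-burst`}{`band` (default `c(20, 45)` Hz), `duty`
#'     (default 0.3): band-limited noise gated by random bursts.}
#'   \item{`lowrank`}{two broadband smooth colored-noise spectral
#'     templates, each gated by a block-wise smooth activation — a
#'     spectrogram of rank about 2, the regime the low-rank separation
#'     model is designed for.}
#' }
#' Every source is scaled to unit RMS and then multiplied by its
#' `amplitude` (default 1, except eye-blink). Fully reproducible from
#' `seed` (R's default Mersenne-Twister generator).
#'
#' @param kinds list of per-source specs: each either a kind string or a
#'   list with `$kind` and parameters.
#' @param fs sampling rate in Hz.
#' @param duration length in seconds (>= 2).
#' @param seed RNG seed.
#' @return list with `S` (sources x samples matrix), `kinds` (character),
#'   `annotations` (per-source list; blink sources carry `event_times` in
#'   seconds).
#' @export
make_sources <- function(kinds, fs, duration, seed = 1) {
  if (duration < 2) stop("spec error: duration must be at least 2 s",
                         call. = FALSE)
  set.seed(seed)
  n <- as.integer(round(fs * duration))
  specs <- lapply(kinds, function(k) if (is.character(k)) list(kind = k)
                  else k)
  S <- matrix(0, length(specs), n)
  ann <- vector("list", length(specs))
  knames <- character(length(specs))
  t_sec <- (0:(n - 1L)) / fs
  for (q in seq_along(specs)) {
    sp <- specs[[q]]
    kind <- sp$kind
    if (is.null(kind) || !kind %in% source_kinds)
      stop("spec error: unknown source kind '", kind, "' (use one of ",
           paste(source_kinds, collapse = ", "), ")", call. = FALSE)
    knames[q] <- kind
    amp <- if (!is.null(sp$amplitude)) sp$amplitude else
      if (kind == "eye-blink") 8 else 1
    if (kind == "neuronal-osc") {
      f0 <- if (!is.null(sp$freq)) sp$freq else 10
      env <- smooth_envelope(n, knots = max(4L, as.integer(duration)))
      x <- env * band_noise(n, fs, max(f0 - 2, 0.5), min(f0 + 2, fs / 2 - 1))
      ann[[q]] <- list(freq = f0)
    } else if (kind == "ssvep") {
      f0 <- if (!is.null(sp$freq)) sp$freq else 12
      if (!any(abs(ssvep_frequencies - f0) < 1e-9))
        stop("spec error: ssvep freq must be one of ",
             paste(ssvep_frequencies, collapse = ", "), " Hz",
             call. = FALSE)
      x <- sin(2 * pi * f0 * t_sec) + 0.5 * sin(2 * pi * 2 * f0 * t_sec)
      ann[[q]] <- list(freq = f0)
    } else if (kind == "eye-blink") {
      interval <- if (!is.null(sp$interval_sec)) sp$interval_sec else 3
      width <- if (!is.null(sp$width_sec)) sp$width_sec else 0.25
      jitter <- if (!is.null(sp$jitter_sec)) sp$jitter_sec else 0
      tmpl <- blink_template(fs, width)
      onsets <- seq(interval / 2, duration - width, by = interval)
      if (jitter > 0)
        onsets <- pmax(0, pmin(duration - width,
                               onsets + stats::runif(length(onsets),
                                                     -jitter, jitter)))
      x <- numeric(n)
      for (on in onsets) {
        i0 <- as.integer(round(on * fs)) + 1L
        idx <- i0:(i0 + length(tmpl) - 1L)
        keep <- idx <= n
        x[idx[keep]] <- x[idx[keep]] + tmpl[keep]
      }
      # slow ocular drift between blinks (sub-1-Hz), as in real eye ICs
      drift_amp <- if (!is.null(sp$drift_amplitude)) sp$drift_amplitude
                   else 0.3
      if (drift_amp > 0) {
        kn <- stats::rnorm(max(4L, as.integer(duration)))
        drift <- stats::approx(seq_along(kn), kn, n = n)$y
        x <- x + drift_amp * drift / stats::sd(drift)
      }
      ann[[q]] <- list(event_times = onsets)
    } else if (kind == "muscle-burst") {
      band <- if (!is.null(sp$band)) sp$band else c(20, 45)
      duty <- if (!is.null(sp$duty)) sp$duty else 0.3
      g <- block_gate(n, fs, duty = duty, block_sec = 1, floor = 0.02)
      x <- g * band_noise(n, fs, band[1L], band[2L])
      ann[[q]] <- list(band = band)
    } else {  # lowrank
      x <- block_gate(n, fs) * colored_noise(n, fs) +
        block_gate(n, fs) * colored_noise(n, fs)
      ann[[q]] <- list()
    }
    r <- sqrt(mean(x^2))
    if (r > 0) x <- x / r
    S[q, ] <- amp * x
  }
  list(S = S, kinds = knames, annotations = ann)
}

#' Distance-attenuated random mixing matrix
#'
#' Gains follow `a_pq = 1 / (1 + d_pq^2)` with `d_pq` the distance from
#' electrode p to source location q, multiplied by a small seeded
#' log-normal perturbation. The perturbation is resampled (up to
#' `max_tries` times) until the condition number is at most `cond_max`.
#'
#' @param layout a [channel_layout()] (P electrodes).
#' @param source_locs Q x 3 matrix of source positions, same frame and
#'   unit as the layout; Q must not exceed P.
#' @param seed RNG seed.
#' @param cond_max condition-number bound (default 100).
#' @param perturb_sd log-scale s.d. of the gain perturbation (default
#'   0.05).
#' @param max_tries resampling budget (default 100).
#' @return P x Q mixing matrix.
#' @export
make_mixing <- function(layout, source_locs, seed = 1, cond_max = 100,
                        perturb_sd = 0.05, max_tries = 100L) {
  stopifnot(inherits(layout, "channel_layout"))
  source_locs <- as.matrix(source_locs)
  P <- length(layout$names); Q <- nrow(source_locs)
  if (Q > P) stop("generation error: more sources than electrodes",
                  call. = FALSE)
  set.seed(seed)
  D <- matrix(0, P, Q)
  for (q in seq_len(Q))
    D[, q] <- sqrt(colSums((t(layout$positions) - source_locs[q, ])^2))
  base <- 1 / (1 + D^2)
  for (try in seq_len(max_tries)) {
    A <- base * exp(matrix(stats::rnorm(P * Q, 0, perturb_sd), P, Q))
    if (kappa(A, exact = TRUE) <= cond_max) return(A)
  }
  stop("generation error: could not reach condition number <= ", cond_max,
       " in ", max_tries, " tries (spread the source locations)",
       call. = FALSE)
}

#' Assemble a synthetic scene
#'
#' @param sources output of [make_sources()].
#' @param A mixing matrix from [make_mixing()].
#' @param layout the [channel_layout()] used for `A`.
#' @param fs sampling rate in Hz.
#' @param noise_sd sensor-noise standard deviation (same unit as the
#'   sources).
#' @param seed RNG seed for the sensor noise.
#' @return A `synthetic_scene` object.
#' @export
make_scene <- function(sources, A, layout, fs, noise_sd = 0.05, seed = 1) {
  A <- as.matrix(A)
  if (nrow(sources$S) != ncol(A))
    stop("spec error: mixing has ", ncol(A), " columns but there are ",
         nrow(sources$S), " sources", call. = FALSE)
  structure(list(sources = sources, A = A, layout = layout, fs = fs,
                 noise_sd = noise_sd, seed = seed),
            class = "synthetic_scene")
}

#' Mix a scene into a recording
#'
#' `X = A S + D` with `D` i.i.d. Gaussian of standard deviation
#' `noise_sd`; with `noise_sd = 0` the output is exactly `A S`.
#'
#' @param scene a `synthetic_scene` from [make_scene()].
#' @return a [recording()].
#' @export
simulate_recording <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  X <- scene$A %*% scene$sources$S
  if (scene$noise_sd > 0) {
    set.seed(scene$seed)
    X <- X + matrix(stats::rnorm(length(X), 0, scene$noise_sd),
                    nrow(X), ncol(X))
  }
  recording(X, scene$fs, scene$layout)
}

#' Approximate 10-20 electrode positions on a unit sphere
#'
#' Positions are constructed from the standard 10% angular subdivisions:
#' sagittal rows Fp/AF/F/FC/C/CP/P/PO/O at 72/54/36/18/0/-18/-36/-54/-72
#' degrees anterior of the vertex and lateral columns z/1-2/3-4/5-6/7-8 at
#' 0/18/36/54/72 degrees (odd digits left). T7/T8 alias C-row 72 degrees;
#' FT and TP alias the FC and CP rows; digits 9/10 sit at 85 degrees.
#' Adequate wherever only relative geometry matters (mixing gains,
#' topographies).
#'
#' @param names character vector of 10-20 labels.
#' @return a [channel_layout()].
#' @export
layout_1020 <- function(names) {
  rows <- c(Fp = 72, AF = 54, F = 36, FC = 18, FT = 18, C = 0, T = 0,
            CP = -18, TP = -18, P = -36, PO = -54, O = -72)
  pos <- t(vapply(names, function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z]+)(z|[0-9]+)$", nm))[[1L]]
    if (length(m) != 3L || !m[2L] %in% names(rows))
      stop("layout error: unrecognised 10-20 label '", nm, "'",
           call. = FALSE)
    alpha <- rows[[m[2L]]] * pi / 180
    if (m[3L] == "z") {
      beta <- 0
    } else {
      d <- as.integer(m[3L])
      width <- c(18, 18, 36, 36, 54, 54, 72, 72, 85, 85)[d]
      beta <- width * pi / 180 * if (d %% 2L == 1L) -1 else 1
    }
    c(sin(beta), cos(beta) * sin(alpha), cos(beta) * cos(alpha))
  }, numeric(3L)))
  channel_layout(names, pos)
}

#' A blink-contaminated SSVEP session
#'
#' Emulates the four-target steady-state visual evoked potential
#' paradigm under ocular contamination: 2-s epochs whose target frequency
#' is drawn from the four stimulation frequencies (5.45, 6.67, 8.57,
#' 12 Hz; sinusoid plus half-amplitude second harmonic, random phase per
#' epoch), two beta-band (13-18 Hz) gated cortical background sources, and a
#' frontal eyeblink train, mixed into the Fp1/Fp2/O1/O2 montage through a
#' distance-attenuated matrix plus white sensor noise. The SSVEP
#' amplitude is kept low relative to the noise so that frequency
#' identification is noise-limited — the regime in which removing the
#' high-variance ocular component can actually help a CCA identifier.
#'
#' @param seed RNG seed driving targets, phases, sources, mixing and
#'   noise.
#' @param n_epochs number of 2-s epochs (default 100, as in a full
#'   training phase).
#' @param fs sampling rate in Hz.
#' @param ssvep_amp RMS amplitude of the SSVEP source (default 0.25).
#' @param blink_amp eyeblink amplitude (default 15).
#' @param noise_sd sensor noise standard deviation (default 0.1).
#' @return list with `epochs` (an `epoch_set`), `targets` (per-epoch
#'   index into the four frequencies), `S` (true sources), `A` (mixing).
#' @export
ssvep_blink_session <- function(seed, n_epochs = 100, fs = 100,
                                ssvep_amp = 0.25, blink_amp = 15,
                                noise_sd = 0.1) {
  set.seed(seed)
  ep_len <- as.integer(2 * fs)
  n <- n_epochs * ep_len
  targets <- sample(seq_along(ssvep_frequencies), n_epochs,
                    replace = TRUE)
  t_sec <- (0:(ep_len - 1L)) / fs
  s_ssvep <- numeric(n)
  for (e in seq_len(n_epochs)) {
    f <- ssvep_frequencies[targets[e]]
    ph <- stats::runif(1) * 2 * pi
    s_ssvep[((e - 1L) * ep_len + 1L):(e * ep_len)] <-
      sin(2 * pi * f * t_sec + ph) +
      0.5 * sin(2 * pi * 2 * f * t_sec + ph)
  }
  s_ssvep <- s_ssvep / sqrt(mean(s_ssvep^2)) * ssvep_amp
  bg <- function(sub) {
    set.seed(seed * 31 + sub)
    x <- block_gate(n, fs) * band_noise(n, fs, 13, 18)
    x <- x / sqrt(mean(x^2))
    # slow-wave floor: cortical background has power down to the
    # slowest frequencies, which keeps the lowest bins well conditioned;
    # kept below the stimulation fundamentals
    fl <- band_noise(n, fs, 0.5, 4.5)
    x + 0.2 * fl / sqrt(mean(fl^2))
  }
  blink <- make_sources(list(list(kind = "eye-blink",
                                  amplitude = blink_amp)),
                        fs, n / fs, seed = seed * 7 + 1)$S[1L, ]
  S <- rbind(s_ssvep, bg(1), bg(2), blink)
  layout <- layout_1020(c("Fp1", "Fp2", "O1", "O2"))
  locs <- rbind(c(0, -0.9, 0.3),   # occipital SSVEP generator
                c(0, 0, 0.8),      # central background
                c(0, -0.4, 0.6),   # parietal background
                c(0, 1.0, 0.1))    # ocular
  A <- make_mixing(layout, locs, seed = seed * 7 + 2)
  set.seed(seed * 7 + 3)
  X <- A %*% S + noise_sd * matrix(stats::rnorm(length(S)), 4L)
  rec <- recording(X, fs, layout)
  eps <- segment_epochs(rec, seq(1L, n - ep_len + 1L, by = ep_len),
                        ep_len)
  list(epochs = eps, targets = targets, S = S, A = A)
}

#' The default four-channel test scene
#'
#' Electrodes Fp1, Fp2, Cz, Oz; sources: a 10-Hz and a 22-Hz
#' amplitude-modulated neuronal oscillation (central and occipital), one
#' frontal eyeblink train and one temporal muscle source — the determined
#' P = Q = 4 case. 60 s at 100 Hz, sensor noise 0.05 of the unit source
#' RMS.
#'
#' @param seed RNG seed driving sources, mixing perturbation and noise.
#' @param duration length in seconds.
#' @param fs sampling rate in Hz.
#' @return a `synthetic_scene`.
#' @export
default_scene <- function(seed = 1, duration = 60, fs = 100) {
  layout <- layout_1020(c("Fp1", "Fp2", "Cz", "Oz"))
  src <- make_sources(list(
    list(kind = "neuronal-osc", freq = 10),
    list(kind = "neuronal-osc", freq = 22),
    list(kind = "eye-blink"),
    list(kind = "muscle-burst")), fs, duration, seed = seed)
  locs <- rbind(c(0, 0, 0.8),        # central neuronal
                c(0, -0.7, 0.5),     # posterior neuronal
                c(0, 1.0, 0.1),      # ocular, above the eyes
                c(0.9, 0.1, 0.1))    # right temporal muscle
  A <- make_mixing(layout, locs, seed = seed + 1)
  make_scene(src, A, layout, fs, noise_sd = 0.05, seed = seed + 2)
}
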