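#' @title Independent-component features and labelling
#' @name component_id
#' @description The three features used to identify estimated ICs — a
#'   32 x 32 scalp topography, a median Welch power spectral density over
#'   1-50 Hz, and a 1-s autocorrelation function — with the scaling
#'   conventions of the identification stage (maximum absolute value 0.99
#'   for topography and PSD, zero-lag value 0.99 for the
#'   autocorrelation), plus a pluggable classifier interface over the
#'   seven-category label set.
NULL

#' The closed label set for independent components
#' @export
ic_labels <- c("brain", "muscle", "eye", "heart", "line noise",
               "channel noise", "other")

#' Collapse a per-bin demixing stack over a frequency band
#'
#' Frequency-mode demixing is a 3-D tensor; for topography it must be
#' reduced to a single matrix. All bins whose centre frequency lies in
#' `band` (inclusive) are summed and the sum is divided by the number of
#' bins; the real part of the result is returned.
#'
#' @param Wstack I x Q x P complex array (or a frequency-mode
#'   `demixing_model`).
#' @param fs sampling rate in Hz.
#' @param band numeric length-2 vector, `c(lo, hi)` in Hz.
#' @param L window length in samples (taken from the model if one is
#'   given); bin i has centre frequency `(i-1) * fs / L`.
#' @return Q x P real matrix.
#' @export
collapse_band <- function(Wstack, fs, band = c(8, 30), L = NULL) {
  if (inherits(Wstack, "demixing_model")) {
    if (Wstack$mode != "frequency")
      stop("band error: frequency-mode model required", call. = FALSE)
    fs <- Wstack$fs; L <- Wstack$L
    Wstack <- Wstack$Wstack
  }
  if (is.null(L)) L <- 2L * (dim(Wstack)[1L] - 1L)
  if (band[1L] > band[2L] || band[1L] < 0 || band[2L] > fs / 2)
    stop("band error: band must lie within [0, ", fs / 2, "] Hz",
         call. = FALSE)
  freqs <- (seq_len(dim(Wstack)[1L]) - 1L) * fs / L
  sel <- which(freqs >= band[1L] & freqs <= band[2L])
  if (!length(sel))
    stop("band error: no frequency bins in [", band[1L], ", ", band[2L],
         "] Hz", call. = FALSE)
  acc <- matrix(0 + 0i, dim(Wstack)[2L], dim(Wstack)[3L])
  for (i in sel) acc <- acc + Wstack[i, , ]
  Re(acc) / length(sel)
}

# azimuthal-equidistant projection of 3-D electrode positions to the unit
# disc: arc distance from the vertex maps to radius (equator -> 1),
# azimuth is preserved; +y (anterior) maps to the top of the image
project_electrodes <- function(positions) {
  p <- positions / sqrt(rowSums(positions^2))
  alpha <- acos(pmin(pmax(p[, 3L], -1), 1))       # polar angle from vertex
  az <- atan2(p[, 1L], p[, 2L])                   # 0 at nose, + to the right
  r <- alpha / (pi / 2)
  cbind(x = r * sin(az), y = r * cos(az))
}

#' Scalp topography image of a mixing column
#'
#' Electrode positions are mapped to the plane by an azimuthal-equidistant
#' projection about the vertex, the column's weights are interpolated to a
#' `size` x `size` grid by inverse-distance weighting (power 2) inside the
#' unit circle, and the image is rescaled to a maximum absolute value of
#' 0.99. Pixels outside the head circle are zero. Row 1 of the image is
#' the front of the head.
#'
#' @param a_q numeric vector of per-channel mixing weights (a column of
#'   the mixing matrix `W^{-1}`).
#' @param layout a [channel_layout()] with at least 3 channels.
#' @param size image side length in pixels (default 32).
#' @return `size` x `size` numeric matrix with `max(abs(.)) = 0.99`
#'   (all-zero for an all-zero column).
#' @export
topography <- function(a_q, layout, size = 32L) {
  stopifnot(inherits(layout, "channel_layout"))
  if (length(a_q) != length(layout$names))
    stop("geometry error: column length ", length(a_q),
         " does not match ", length(layout$names), " channels",
         call. = FALSE)
  if (length(a_q) < 3L)
    stop("geometry error: at least 3 channels required", call. = FALSE)
  xy <- project_electrodes(layout$positions)
  g <- seq(-1, 1, length.out = size)
  img <- matrix(0, size, size)
  if (all(a_q == 0)) return(img)
  for (r in seq_len(size)) {
    gy <- g[size - r + 1L]  # row 1 = top = front
    for (c in seq_len(size)) {
      gx <- g[c]
      if (gx^2 + gy^2 > 1) next
      d2 <- (xy[, 1L] - gx)^2 + (xy[, 2L] - gy)^2
      hit <- d2 < 1e-12
      if (any(hit)) {
        img[r, c] <- a_q[which(hit)[1L]]
      } else {
        w <- 1 / d2
        img[r, c] <- sum(w * a_q) / sum(w)
      }
    }
  }
  img * (0.99 / max(abs(img)))
}

#' Median Welch power spectral density on a 1-50 Hz grid
#'
#' 1-s periodic-Hamming segments with 50% overlap; the per-bin MEDIAN
#' across segment periodograms replaces the usual mean, the result is
#' converted to decibels and rescaled to a maximum absolute value of 0.99.
#'
#' @param ic numeric time series of one independent component.
#' @param fs sampling rate in Hz (integer-valued so the bin grid is 1 Hz).
#' @return numeric vector of scaled dB values on the 1-50 Hz grid (upper
#'   limit `min(50, fs/2 - 1)`), with attributes `freq` (Hz) and
#'   `power` (unscaled linear median periodogram over the full band, named
#'   by frequency), the latter used by score-based classifiers.
#' @export
median_psd <- function(ic, fs) {
  if (length(ic) < 2 * fs)
    stop("length error: need at least 2 s of data (", 2 * fs,
         " samples), got ", length(ic), call. = FALSE)
  L <- as.integer(round(fs)); H <- L %/% 2L
  J <- 1L + (length(ic) - L) %/% H
  w <- hamming_periodic(L)
  I <- L %/% 2L + 1L
  pg <- matrix(0, I, J)
  for (j in seq_len(J)) {
    seg <- ic[((j - 1L) * H + 1L):((j - 1L) * H + L)] * w
    pg[, j] <- Mod(stats::fft(seg)[1:I])^2 / (sum(w^2) * fs)
  }
  medp <- apply(pg, 1L, stats::median)
  freqs <- (0:(L %/% 2L)) * fs / L
  names(medp) <- freqs
  hi <- min(50, floor(fs / 2) - 1)
  sel <- which(freqs >= 1 & freqs <= hi)
  db <- 10 * log10(pmax(medp[sel], 1e-300))
  scaled <- db * (0.99 / max(abs(db)))
  attr(scaled, "freq") <- freqs[sel]
  attr(scaled, "power") <- medp
  scaled
}

#' Normalised autocorrelation over lags 0 to fs-1
#'
#' Biased sample autocorrelation up to a 1-s lag, divided by the zero-lag
#' value and multiplied by 0.99 (so `acf[1] == 0.99` exactly).
#'
#' @param ic numeric time series (length > fs, nonconstant).
#' @param fs sampling rate in Hz.
#' @return numeric vector of length `fs` (lags 0..fs-1).
#' @export
autocorr <- function(ic, fs) {
  if (length(ic) <= fs)
    stop("length error: need more than ", fs, " samples", call. = FALSE)
  if (stats::var(ic) == 0)
    stop("degeneracy error: constant signal has undefined autocorrelation",
         call. = FALSE)
  a <- as.numeric(stats::acf(ic, lag.max = fs - 1L, type = "correlation",
                             plot = FALSE, demean = TRUE)$acf)
  a / a[1L] * 0.99  # exact 0.99 at lag zero
}

#' Bundle the three identification features of one IC
#'
#' @param ic numeric time series of the component.
#' @param mixing_column per-channel weights of the component in the mixing
#'   matrix (for frequency-mode models: a column of the inverse of the
#'   band-collapsed demixing matrix, see [collapse_band()]).
#' @param layout a [channel_layout()].
#' @param fs sampling rate in Hz.
#' @param power_share optional fraction (0..1) of the total reconstructed
#'   signal variance carried by this component; amplitude-aware
#'   classifiers use it to veto artifact labels for negligible
#'   components.
#' @return An `ic_features` object: `topo` (32 x 32), `psd`, `acf`,
#'   `power_share`.
#' @export
ic_features <- function(ic, mixing_column, layout, fs,
                        power_share = NULL) {
  structure(list(topo = topography(mixing_column, layout),
                 psd = median_psd(ic, fs),
                 acf = autocorr(ic, fs),
                 power_share = power_share),
            class = "ic_features")
}

#' Heuristic score-based IC classifier
#'
#' A documented stand-in classifier exposing the plug-in contract: it
#' labels a component "eye" when the fraction of spectral power below
#' `f_low_hz` exceeds `theta_eye` AND the fraction of absolute topographic
#' mass in the frontal third of the image exceeds `theta_front`; "muscle"
#' when the fraction of power above `f_high_hz` exceeds `theta_musc`;
#' otherwise "brain". It never emits the remaining four labels.
#' Confidences are the normalised rule scores.
#'
#' The frontal-mass scale is set by the topography construction: a
#' spatially uniform field puts about 0.26 of its mass in the frontal
#' third (the area fraction), while an ideal ocular column (unit weight
#' at the most frontal electrodes) reaches only about 0.40-0.42 because
#' inverse-distance interpolation spreads mass across the whole disc.
#' The default threshold 0.33 sits between those two bounds.
#'
#' Because biological artifacts carry high-amplitude potentials, a
#' component is only eligible for an artifact label when its share of the
#' total reconstructed variance (when known, see [ic_features()])
#' exceeds `theta_power`: a component contributing a negligible fraction
#' of the signal cannot be the artifact worth removing.
#'
#' @param theta_eye low-frequency power-fraction threshold (default 0.4).
#' @param theta_front frontal-mass threshold (default 0.33).
#' @param theta_musc high-frequency power-fraction threshold (default
#'   0.35).
#' @param theta_power minimum variance share for any artifact label
#'   (default 0.1; ignored when the feature is absent).
#' @param f_low_hz "low" band upper edge in Hz (default 3).
#' @param f_high_hz "high" band lower edge in Hz (default 20).
#' @return a classifier function `f(features)` returning a named numeric
#'   vector of 7 scores over [ic_labels].
#' @export
heuristic_classifier <- function(theta_eye = 0.4, theta_front = 0.33,
                                 theta_musc = 0.35, theta_power = 0.1,
                                 f_low_hz = 3, f_high_hz = 20) {
  force(theta_eye); force(theta_front); force(theta_musc)
  function(features) {
    stopifnot(inherits(features, "ic_features"))
    pw <- attr(features$psd, "power")
    freqs <- as.numeric(names(pw))
    tot <- sum(pw)
    f_low <- if (tot > 0) sum(pw[freqs < f_low_hz]) / tot else 0
    f_high <- if (tot > 0) sum(pw[freqs > f_high_hz]) / tot else 0
    topo <- features$topo
    front_rows <- seq_len(nrow(topo) %/% 3L)
    mass <- sum(abs(topo))
    f_front <- if (mass > 0) sum(abs(topo[front_rows, ])) / mass else 0
    big_enough <- is.null(features$power_share) ||
      features$power_share > theta_power
    is_eye <- big_enough && f_low > theta_eye && f_front > theta_front
    is_musc <- big_enough && !is_eye && f_high > theta_musc
    s <- stats::setNames(numeric(7L), ic_labels)
    s["eye"] <- f_low * f_front
    s["muscle"] <- f_high
    s["brain"] <- max(1 - f_low * f_front - f_high, 0.05)
    # the rule decision dominates the scores so label == argmax
    if (is_eye) s["eye"] <- max(s) + 1
    else if (is_musc) s["muscle"] <- max(s) + 1
    else s["brain"] <- max(s) + 1
    s / sum(s)
  }
}

#' Classify a list of IC feature sets
#'
#' @param features list of `ic_features` objects.
#' @param classifier a function taking one `ic_features` and returning a
#'   named numeric vector of 7 nonnegative scores over [ic_labels]
#'   (defaults to [heuristic_classifier()]).
#' @return data.frame with columns `index`, `label`, plus one confidence
#'   column per category (rows sum to 1).
#' @export
classify_components <- function(features, classifier = NULL) {
  if (is.null(classifier)) classifier <- heuristic_classifier()
  rows <- lapply(seq_along(features), function(i) {
    s <- classifier(features[[i]])
    if (is.null(names(s)) || !setequal(names(s), ic_labels) ||
        any(s < 0) || !all(is.finite(s)))
      stop("contract error: classifier must return nonnegative scores ",
           "named by the 7 component categories", call. = FALSE)
    s <- s[ic_labels] / sum(s)
    data.frame(index = i, label = ic_labels[which.max(s)],
               t(as.matrix(s)), check.names = FALSE)
  })
  do.call(rbind, rows)
}
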