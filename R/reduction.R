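#' @title Label-driven artifact removal and signal reconstruction
#' @name reduction
#' @description Components labelled "eye" or "muscle" are zeroed in the
#'   source domain and the remaining sources are remixed: time-domain
#'   models invert the comprehensive demixing matrix; frequency-domain
#'   models zero the component across all bins and frames, invert each
#'   per-bin demixing matrix, and resynthesise by inverse STFT.
NULL

#' Remove components from a time-domain mixture
#'
#' @param X channels x samples matrix.
#' @param model time-mode `demixing_model`.
#' @param drop integer indices of components to zero (may be empty).
#' @return cleaned channels x samples matrix `W^{-1} M W X`, where M zeros
#'   the dropped rows.
#' @export
remove_components_time <- function(X, model, drop = integer()) {
  stopifnot(inherits(model, "demixing_model"))
  if (model$mode != "time")
    stop("shape error: time-mode model required", call. = FALSE)
  X <- as.matrix(X)
  Q <- nrow(model$W)
  drop <- as.integer(drop)
  if (length(drop) && (any(drop < 1L) || any(drop > Q)))
    stop("index error: component indices must be in 1..", Q, call. = FALSE)
  S <- apply_demixing(model, X)
  if (length(drop)) S[drop, ] <- 0
  apply_mixing(model, S)
}

#' Remove components from a frequency-domain mixture
#'
#' @param spec mixture `spectrogram`.
#' @param model frequency-mode `demixing_model`.
#' @param drop integer indices of components to zero across all bins and
#'   frames.
#' @param out_length number of time samples to synthesise.
#' @return cleaned channels x `out_length` matrix.
#' @export
remove_components_freq <- function(spec, model, drop = integer(),
                                   out_length = NULL) {
  stopifnot(inherits(spec, "spectrogram"), inherits(model, "demixing_model"))
  if (model$mode != "frequency")
    stop("shape error: frequency-mode model required", call. = FALSE)
  d <- dim(spec$tensor)
  Q <- dim(model$Wstack)[2L]
  drop <- as.integer(drop)
  if (length(drop) && (any(drop < 1L) || any(drop > Q)))
    stop("index error: component indices must be in 1..", Q, call. = FALSE)
  Y <- apply_demixing_freq(model, spec)
  if (length(drop)) Y$tensor[drop, , ] <- 0
  Xt <- array(0 + 0i, dim(spec$tensor))
  for (i in seq_len(d[2L])) {
    Yi <- Y$tensor[, i, , drop = TRUE]
    if (Q == 1L) Yi <- matrix(Yi, 1L)
    Xt[, i, ] <- model$Astack[i, , ] %*% Yi
  }
  clean <- structure(list(tensor = Xt, fs = spec$fs, L = spec$L,
                          H = spec$H, window = spec$window),
                     class = "spectrogram")
  istft(clean, out_length)
}

#' Per-source time-domain images of a frequency-mode separation
#'
#' Projects each estimated source back through its column of the per-bin
#' mixing matrix (`W_i^{-1}`), giving the source's contribution at every
#' channel with correct per-bin scaling, then inverse transforms.
#'
#' @param model frequency-mode `demixing_model`.
#' @param Y source `spectrogram` (Q x I x J), e.g. from [fit_ilrma()] or
#'   [apply_demixing_freq()].
#' @param out_length number of time samples to synthesise.
#' @return array sources x channels x samples.
#' @export
source_images <- function(model, Y, out_length = NULL) {
  stopifnot(inherits(model, "demixing_model"),
            inherits(Y, "spectrogram"))
  if (model$mode != "frequency")
    stop("shape error: frequency-mode model required", call. = FALSE)
  d <- dim(Y$tensor)  # Q x I x J
  Q <- d[1L]; I <- d[2L]; J <- d[3L]
  P <- dim(model$Astack)[2L]
  if (is.null(out_length)) out_length <- Y$L + (J - 1L) * Y$H
  out <- array(0, c(Q, P, out_length))
  for (q in seq_len(Q)) {
    img <- array(0 + 0i, c(P, I, J))
    for (i in seq_len(I))
      img[, i, ] <- outer(model$Astack[i, , q], Y$tensor[q, i, ])
    sp <- structure(list(tensor = img, fs = Y$fs, L = Y$L, H = Y$H,
                         window = Y$window), class = "spectrogram")
    out[q, , ] <- istft(sp, out_length)
  }
  out
}

#' Train-and-apply artifact reduction pipeline
#'
#' Fits one demixing model on the concatenated training epochs (each epoch
#' STFT-framed independently for the frequency-domain methods, so no frame
#' spans an epoch boundary), extracts the three IC features, labels every
#' component, and removes the components whose label is in `remove_labels`
#' from every epoch of `apply_to`.
#'
#' @param train `epoch_set` used to fit the demixing model.
#' @param apply_to `epoch_set` to clean (same channel count and fs).
#' @param method `"ica"`, `"iva"` or `"ilrma"`.
#' @param band frequency band (Hz) over which frequency-mode demixing
#'   stacks are collapsed for topography (default `c(8, 30)`).
#' @param classifier classifier function (default
#'   [heuristic_classifier()]).
#' @param remove_labels labels to remove (default `c("eye", "muscle")`).
#' @param seed RNG seed passed to the fitting routine.
#' @param ... further arguments passed to the fitting routine
#'   ([fit_infomax_ica()], [fit_iva()] or [fit_ilrma()]).
#' @return list with `epochs` (cleaned `epoch_set`), `report` (labels,
#'   confidences, dropped indices, method, seed, and the ILRMA cost trace
#'   when applicable), and `model`.
#' @export
reduce_pipeline <- function(train, apply_to, method = c("ilrma", "ica",
                                                        "iva"),
                            band = c(8, 30), classifier = NULL,
                            remove_labels = c("eye", "muscle"),
                            seed = NULL, ...) {
  stopifnot(inherits(train, "epoch_set"), inherits(apply_to, "epoch_set"))
  method <- match.arg(method)
  if (dim(train$epochs)[2L] != dim(apply_to$epochs)[2L])
    stop("stage separate: channel counts differ between train and apply ",
         "sets", call. = FALSE)
  layout <- train$layout
  if (is.null(layout))
    stop("stage identify: epoch set carries no channel layout",
         call. = FALSE)
  fs <- train$fs
  P <- dim(train$epochs)[2L]
  cost_trace <- NULL
  if (method == "ica") {
    X <- epochs_to_matrix(train)
    model <- withCallingHandlers(
      fit_infomax_ica(X, seed = seed, ...),
      error = function(e) stop("stage separate: ", conditionMessage(e),
                               call. = FALSE))
    S <- apply_demixing(model, X)
    mix_cols <- model$A
    pwr <- colSums(abs(model$A)^2) * rowSums(S^2)
  } else {
    es <- epochs_to_spectrogram(train)
    fitfun <- if (method == "iva") {
      function() fit_iva(es$spec, seed = seed, ...)
    } else {
      function() fit_ilrma(es$spec, seed = seed, ...)
    }
    fit <- tryCatch(fitfun(), error = function(e)
      stop("stage separate: ", conditionMessage(e), call. = FALSE))
    if (method == "ilrma") {
      model <- fit$model
      Yspec <- fit$Y
      cost_trace <- fit$cost_trace
    } else {
      model <- fit
      Yspec <- apply_demixing_freq(model, es$spec)
    }
    Wc <- collapse_band(model, band = band)
    mix_cols <- tryCatch(solve(Wc), error = function(e)
      stop("stage identify: collapsed demixing matrix not invertible",
           call. = FALSE))
    # per-IC time series for the features: the back-projected source
    # image at the component's dominant channel, reconstructed epoch by
    # epoch (back-projection restores consistent per-bin scaling)
    dom <- apply(abs(mix_cols), 2L, which.max)
    Je <- es$frames_per_epoch
    S <- matrix(0, P, es$n_epochs * es$epoch_length)
    I <- dim(Yspec$tensor)[2L]
    for (q in seq_len(P)) {
      proj <- array(0 + 0i, c(1L, I, dim(Yspec$tensor)[3L]))
      for (i in seq_len(I))
        proj[1L, i, ] <- model$Astack[i, dom[q], q] * Yspec$tensor[q, i, ]
      for (t in seq_len(es$n_epochs)) {
        sub <- structure(list(
          tensor = proj[, , ((t - 1L) * Je + 1L):(t * Je), drop = FALSE],
          fs = fs, L = Yspec$L, H = Yspec$H, window = Yspec$window),
          class = "spectrogram")
        S[q, ((t - 1L) * es$epoch_length + 1L):(t * es$epoch_length)] <-
          istft(sub, es$epoch_length)
      }
    }
    # each component's share of the reconstructed signal variance
    pwr <- vapply(seq_len(P), function(q) {
      cn <- rowSums(abs(model$Astack[, , q, drop = FALSE])^2)  # per bin
      sum(cn * rowSums(Mod(Yspec$tensor[q, , , drop = FALSE][1L, , ])^2))
    }, numeric(1L))
  }
  shares <- pwr / sum(pwr)
  feats <- lapply(seq_len(P), function(q)
    ic_features(S[q, ], mix_cols[, q], layout, fs,
                power_share = shares[q]))
  labs <- tryCatch(classify_components(feats, classifier),
                   error = function(e)
                     stop("stage identify: ", conditionMessage(e),
                          call. = FALSE))
  dropped <- which(labs$label %in% remove_labels)
  # apply to every epoch
  d <- dim(apply_to$epochs)
  clean <- apply_to
  for (t in seq_len(d[1L])) {
    Xe <- apply_to$epochs[t, , , drop = TRUE]
    if (d[2L] == 1L) Xe <- matrix(Xe, 1L)
    if (method == "ica") {
      clean$epochs[t, , ] <- remove_components_time(Xe, model, dropped)
    } else {
      spe <- stft(Xe, fs = fs)
      clean$epochs[t, , ] <- remove_components_freq(spe, model, dropped,
                                                    out_length = d[3L])
    }
  }
  report <- list(method = method, seed = seed, band = band,
                 labels = labs$label, confidence = labs,
                 dropped = dropped, remove_labels = remove_labels,
                 cost_trace = cost_trace)
  list(epochs = clean, report = report, model = model)
}
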