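#' @title Independent low-rank matrix analysis
#' @name bss_ilrma
#' @description Determined frequency-domain BSS in which each source's
#'   spectrogram variance is modelled as a low-rank nonnegative product of
#'   spectral bases and temporal activations, with a partitioning function
#'   softly assigning each of the K bases to a source. The demixing
#'   matrices are updated by iterative projection (an auxiliary-function
#'   technique) and the source model by majorization-minimization
#'   multiplicative updates, so the joint cost never increases.
NULL

ilrma_eps <- 1e-12

#' Construct an ILRMA source model
#'
#' @param Tm spectral bases, I x K nonnegative matrix (shared pool).
#' @param V temporal activations, K x J nonnegative matrix.
#' @param Z partitioning function, Q x K with columns summing to one.
#' @return An `ilrma_source_model` with the variance model `R`
#'   (`r_ijq = sum_k z_qk t_ik v_kj`, floored at 1e-12) kept in sync.
#' @export
ilrma_source_model <- function(Tm, V, Z) {
  Tm <- pmax(as.matrix(Tm), ilrma_eps)
  V <- pmax(as.matrix(V), ilrma_eps)
  Z <- as.matrix(Z)
  if (ncol(Tm) != nrow(V) || ncol(Tm) != ncol(Z))
    stop("shape error: basis count K inconsistent between T, V, Z",
         call. = FALSE)
  if (any(Z < 0)) stop("partitioning entries must be nonnegative",
                       call. = FALSE)
  m <- structure(list(T = Tm, V = V, Z = Z, K = ncol(Tm),
                      lambda = rep(1, nrow(Z)), R = NULL),
                 class = "ilrma_source_model")
  sync_variance(m)
}

# recompute R from T, V, Z (exact resync, with floor)
sync_variance <- function(model) {
  I <- nrow(model$T); J <- ncol(model$V); Q <- nrow(model$Z)
  R <- array(0, c(I, J, Q))
  for (q in seq_len(Q))
    R[, , q] <- pmax(model$T %*% (model$Z[q, ] * model$V), ilrma_eps)
  model$R <- R
  model
}

#' @export
print.ilrma_source_model <- function(x, ...) {
  cat("<ilrma_source_model> ", nrow(x$Z), " sources, K=", x$K, " bases, ",
      nrow(x$T), " bins x ", ncol(x$V), " frames\n", sep = "")
  invisible(x)
}

#' ILRMA cost function
#'
#' `sum_ij { sum_q log r_ijq + sum_q |y_ijq|^2 / r_ijq
#'   - 2 log|det W_i| }`: the negative log-likelihood of the per-bin
#' complex Gaussian source model with low-rank variances.
#'
#' @param Wstack per-bin demixing stack, I x Q x P complex array.
#' @param Y source spectrogram values, I x J x Q complex array.
#' @param model an `ilrma_source_model` with `R` in sync.
#' @return scalar cost.
#' @export
ilrma_cost <- function(Wstack, Y, model) {
  R <- model$R
  if (any(R <= 0)) stop("domain error: nonpositive source variance",
                        call. = FALSE)
  if (!identical(dim(R), dim(Y)))
    stop("shape error: Y and variance model disagree", call. = FALSE)
  J <- dim(Y)[2L]
  ld <- 0
  for (i in seq_len(dim(Wstack)[1L]))
    ld <- ld + sum(log(La.svd(Wstack[i, , ])$d))
  sum(log(R)) + sum(Mod(Y)^2 / R) - 2 * J * ld
}

#' Majorization-minimization update of the ILRMA source model
#'
#' One sweep of multiplicative updates for the partitioning function Z,
#' the bases T and the activations V (in that order, each followed by an
#' exact variance resync). After the Z update its columns are renormalised
#' to sum to one over sources, with the column sums absorbed into T so the
#' variance model is unchanged. Nonnegativity is preserved and every entry
#' stays at or above the 1e-12 floor; the cost ([ilrma_cost()]) never
#' increases.
#'
#' @param model an `ilrma_source_model`.
#' @param Y source spectrogram values, I x J x Q complex (or numeric
#'   magnitude-squared-compatible) array.
#' @return the updated `ilrma_source_model`.
#' @export
update_source_model <- function(model, Y) {
  stopifnot(inherits(model, "ilrma_source_model"))
  Q <- nrow(model$Z); K <- model$K
  I <- nrow(model$T); J <- ncol(model$V)
  Pw <- Mod(Y)^2
  eps <- ilrma_eps
  # Z update
  num <- matrix(0, Q, K); den <- matrix(0, Q, K)
  for (q in seq_len(Q)) {
    E <- Pw[, , q] / model$R[, , q]^2
    Fm <- 1 / model$R[, , q]
    num[q, ] <- colSums(model$T * (E %*% t(model$V)))
    den[q, ] <- colSums(model$T * (Fm %*% t(model$V)))
  }
  model$Z <- model$Z * sqrt(num / pmax(den, eps))
  ck <- pmax(colSums(model$Z), eps)
  model$Z <- sweep(model$Z, 2L, ck, "/")
  model$T <- pmax(sweep(model$T, 2L, ck, "*"), eps)
  model <- sync_variance(model)
  # T update
  num <- matrix(0, I, K); den <- matrix(0, I, K)
  for (q in seq_len(Q)) {
    E <- Pw[, , q] / model$R[, , q]^2
    Fm <- 1 / model$R[, , q]
    num <- num + sweep(E %*% t(model$V), 2L, model$Z[q, ], "*")
    den <- den + sweep(Fm %*% t(model$V), 2L, model$Z[q, ], "*")
  }
  model$T <- pmax(model$T * sqrt(num / pmax(den, eps)), eps)
  model <- sync_variance(model)
  # V update
  num <- matrix(0, K, J); den <- matrix(0, K, J)
  for (q in seq_len(Q)) {
    E <- Pw[, , q] / model$R[, , q]^2
    Fm <- 1 / model$R[, , q]
    num <- num + model$Z[q, ] * (t(model$T) %*% E)
    den <- den + model$Z[q, ] * (t(model$T) %*% Fm)
  }
  model$V <- pmax(model$V * sqrt(num / pmax(den, eps)), eps)
  sync_variance(model)
}

#' Iterative-projection update of the per-bin demixing matrices
#'
#' For every bin i and source q (in order q = 1..Q): the weighted
#' covariance `V_iq = (1/J) sum_j x_ij x_ij^H / r_ijq` is formed, the row
#' is updated by `w_iq <- (W_i V_iq)^{-1} e_q` and normalised so that
#' `w_iq^H V_iq w_iq = 1`. A singular system triggers a diagonal-loading
#' fallback (`delta = 1e-12 * trace/Q`) with a warning. The source
#' spectrogram is recomputed exactly as `y_ijq = w_iq^H x_ij`.
#'
#' @param Wstack per-bin demixing stack, I x Q x P complex array.
#' @param X mixture `spectrogram` (P x I x J tensor).
#' @param model an `ilrma_source_model` with `R` in sync.
#' @return list with updated `Wstack` and `Y` (I x J x Q complex array).
#' @export
update_demixing <- function(Wstack, X, model) {
  tens <- if (inherits(X, "spectrogram")) X$tensor else X
  P <- dim(tens)[1L]; I <- dim(tens)[2L]; J <- dim(tens)[3L]
  Q <- dim(Wstack)[2L]
  if (P != Q)
    stop("determinedness error: P = ", P, " channels but Q = ", Q,
         " sources; ILRMA requires P = Q", call. = FALSE)
  Y <- array(0 + 0i, c(I, J, Q))
  eq <- diag(Q)
  logdet <- function(M) sum(log(La.svd(M)$d))
  for (i in seq_len(I)) {
    Xi <- tens[, i, , drop = TRUE]
    if (P == 1L) Xi <- matrix(Xi, 1L)
    Wi <- Wstack[i, , ]
    rinv <- 1 / model$R[i, , , drop = FALSE]  # 1 x J x Q
    for (q in seq_len(Q)) {
      wts <- rinv[1L, , q]
      Viq <- (Xi * rep(wts, each = P)) %*% Conj(t(Xi)) / J
      # the weighted power sum evaluated directly: all-positive, immune
      # to the cancellation that makes w^H V w inaccurate when the
      # weights span many orders of magnitude
      wpow <- function(w) sum(Mod(Conj(w) %*% Xi)^2 * wts) / J
      solve_row <- function(V) {
        w <- tryCatch(solve(Wi %*% V, eq[, q]), error = function(e) NULL)
        if (is.null(w) || !all(is.finite(w))) return(NULL)
        nrm2 <- wpow(w)
        if (!is.finite(nrm2) || nrm2 <= 0) return(NULL)
        w / sqrt(nrm2)
      }
      w <- solve_row(Viq)
      if (is.null(w)) {
        delta <- 1e-12 * Re(sum(diag(Viq))) / Q
        warning("singular system at bin ", i, ", source ", q,
                "; applying diagonal loading", call. = FALSE)
        tries <- 0L
        repeat {
          w <- solve_row(Viq + delta * diag(Q))
          tries <- tries + 1L
          if (!is.null(w) || tries >= 20L) break
          delta <- delta * 100
        }
      }
      if (!is.null(w)) {
        # accept the iterative-projection row only if it does not
        # increase the bin-local objective (the solve itself can lose
        # precision at extreme weightings); otherwise keep the old row
        w_old <- Conj(Wi[q, ])
        Wnew <- Wi
        Wnew[q, ] <- Conj(w)
        dlocal <- (1 - wpow(w_old)) - 2 * (logdet(Wnew) - logdet(Wi))
        if (is.finite(dlocal) && dlocal <= 1e-12) Wi <- Wnew
      }
    }
    Wstack[i, , ] <- Wi
    Y[i, , ] <- t(Wi %*% Xi)
  }
  list(Wstack = Wstack, Y = Y)
}

#' Per-iteration scale normalisation
#'
#' Computes `lambda_q = sqrt((1/IJ) sum_ij |y_ijq|^2)` and rescales
#' `w_iq <- w_iq / lambda_q`, `y_ijq <- y_ijq / lambda_q` and the variance
#' model `r_ijq <- r_ijq / lambda_q^2` (realised by `z_qk <- z_qk /
#' lambda_q^2`, after which Z columns are renormalised to sum to one with
#' the column sums absorbed into T, leaving the variances unchanged).
#' Afterwards every source has unit mean power and all `|y|^2 / r` ratios
#' are exactly as before. An all-zero source gets `lambda = 1` with a
#' warning.
#'
#' @inheritParams ilrma_cost
#' @return list with rescaled `Wstack`, `Y` and `model` (its `lambda`
#'   field holds the scales that were removed).
#' @export
normalize_model <- function(Wstack, Y, model) {
  stopifnot(inherits(model, "ilrma_source_model"))
  Q <- nrow(model$Z)
  lam <- sqrt(apply(Mod(Y)^2, 3L, mean))
  zero <- lam <= 0
  if (any(zero)) {
    warning("silent source(s) ", paste(which(zero), collapse = ", "),
            ": scale left at 1", call. = FALSE)
    lam[zero] <- 1
  }
  for (q in seq_len(Q)) {
    Wstack[, q, ] <- Wstack[, q, ] / lam[q]
    Y[, , q] <- Y[, , q] / lam[q]
    model$Z[q, ] <- model$Z[q, ] / lam[q]^2
  }
  ck <- pmax(colSums(model$Z), ilrma_eps)
  model$Z <- sweep(model$Z, 2L, ck, "/")
  model$T <- sweep(model$T, 2L, ck, "*")
  model$lambda <- lam
  model <- sync_variance(model)
  list(Wstack = Wstack, Y = Y, model = model)
}

#' Fit ILRMA
#'
#' Runs exactly `iters` iterations of [update_source_model()] →
#' [update_demixing()] → [normalize_model()] from deterministic seeded
#' initial conditions (`W_i` = identity, T and V i.i.d. Uniform(0,1), Z
#' uniform at 1/Q). The basis count defaults to `K = max(1, floor(J/10))`.
#'
#' @param spec mixture `spectrogram` (see [stft()]); channel count must
#'   equal the source count (determined case).
#' @param K number of bases, or `"auto"` for `max(1, floor(J/10))`.
#' @param iters number of iterations (default 200).
#' @param seed RNG seed for the T/V initialisation.
#' @return list with `model` (frequency-mode `demixing_model`),
#'   `source_model` (`ilrma_source_model`), `Y` (source `spectrogram`),
#'   and `cost_trace` (length `iters + 1`, non-increasing).
#' @export
fit_ilrma <- function(spec, K = "auto", iters = 200L, seed = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  tens <- spec$tensor
  P <- dim(tens)[1L]; I <- dim(tens)[2L]; J <- dim(tens)[3L]
  Q <- P
  if (J < 2L) stop("precondition error: need at least 2 frames",
                   call. = FALSE)
  if (identical(K, "auto")) K <- max(1L, J %/% 10L)
  K <- as.integer(K)
  if (!is.null(seed)) set.seed(seed)
  Wstack <- array(0 + 0i, c(I, Q, P))
  for (i in seq_len(I)) Wstack[i, , ] <- diag(Q)
  model <- ilrma_source_model(matrix(stats::runif(I * K), I, K),
                              matrix(stats::runif(K * J), K, J),
                              matrix(1 / Q, Q, K))
  Y <- array(0 + 0i, c(I, J, Q))
  for (i in seq_len(I)) {
    Xi <- tens[, i, , drop = TRUE]
    if (P == 1L) Xi <- matrix(Xi, 1L)
    Y[i, , ] <- t(Xi)
  }
  trace <- numeric(iters + 1L)
  trace[1L] <- ilrma_cost(Wstack, Y, model)
  for (it in seq_len(iters)) {
    model <- update_source_model(model, Y)
    upd <- update_demixing(Wstack, spec, model)
    Wstack <- upd$Wstack
    Y <- upd$Y
    nm <- normalize_model(Wstack, Y, model)
    Wstack <- nm$Wstack; Y <- nm$Y; model <- nm$model
    trace[it + 1L] <- ilrma_cost(Wstack, Y, model)
  }
  dm <- demixing_model_freq(Wstack, fs = spec$fs, L = spec$L, H = spec$H,
                            iterations = iters, K = K)
  Yspec <- structure(list(tensor = aperm(Y, c(3L, 1L, 2L)), fs = spec$fs,
                          L = spec$L, H = spec$H, window = spec$window),
                     class = "spectrogram")
  list(model = dm, source_model = model, Y = Yspec, cost_trace = trace)
}
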