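#' @title Extended infomax independent component analysis
#' @name bss_ica
#' @description Time-domain determined BSS: the data are decorrelated by a
#'   whitening matrix W1, then a square demixing matrix W2 is learned by
#'   natural-gradient likelihood ascent with a score function switched
#'   between super- and sub-Gaussian by the sign of each source's fourth
#'   cumulant. The comprehensive demixing matrix is W = W2 W1.
NULL

#' Whiten a multichannel signal
#'
#' Removes row means and applies `W1 = D^{-1/2} E^T` from the
#' eigendecomposition of the sample covariance, so that the output has
#' identity covariance.
#'
#' @param X channels x samples numeric matrix.
#' @param tol relative eigenvalue threshold below which the covariance is
#'   declared rank deficient.
#' @return list with `W1` (whitening matrix), `Xw` (whitened data),
#'   `means` (removed row means).
#' @export
whiten <- function(X, tol = 1e-10) {
  X <- as.matrix(X)
  if (ncol(X) <= nrow(X))
    stop("degeneracy error: need more samples than channels", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < tol * max(e$values)))
    stop("degeneracy error: covariance is rank deficient (eigenvalue ",
         format(min(e$values)), ")", call. = FALSE)
  W1 <- diag(1 / sqrt(e$values), nrow(X)) %*% t(e$vectors)
  list(W1 = W1, Xw = W1 %*% Xc, means = mu)
}

#' Empirical fourth cumulant
#'
#' `c4 = M4 - 3 M2^2` with moments taken about the sample mean. Negative
#' for sub-Gaussian (e.g. uniform), positive for super-Gaussian (e.g.
#' Laplacian), near zero for Gaussian samples.
#'
#' @param s numeric sample vector (length >= 4).
#' @return scalar fourth cumulant.
#' @export
fourth_cumulant <- function(s) {
  if (length(s) < 4L) stop("need at least 4 samples", call. = FALSE)
  s <- s - mean(s)
  mean(s^4) - 3 * mean(s^2)^2
}

#' Extended infomax score function
#'
#' `phi(s) = -(s + sign(c4) * tanh(s))`, evaluated elementwise: the
#' super-Gaussian score for `c4_sign = +1`, the sub-Gaussian score for
#' `c4_sign = -1`.
#'
#' @param s numeric vector of source values.
#' @param c4_sign +1 or -1.
#' @return numeric vector of score values.
#' @export
infomax_score <- function(s, c4_sign) {
  -(s + sign(c4_sign) * tanh(s))
}

#' Fit extended infomax ICA
#'
#' After whitening, `W2` (initialised at identity) is updated by the
#' natural-gradient rule `W2 <- W2 + eta * (I + E[phi(s) s^T]) W2`, the
#' expectation being the full-batch sample mean; each source's score is
#' re-selected every iteration from the sign of its fourth cumulant.
#' Iteration stops when `||dW||_F / ||W2||_F < tol` or after `max_iter`
#' steps.
#'
#' @param X channels x samples matrix, or a [recording()].
#' @param eta learning rate (dimensionless step on the natural gradient).
#' @param max_iter maximum number of full-batch iterations.
#' @param tol relative Frobenius-norm convergence threshold.
#' @param seed optional RNG seed (the algorithm is deterministic; the seed
#'   is recorded for provenance only).
#' @return A `demixing_model` in time mode: `W1`, `W2`, `W = W2 W1`,
#'   cached inverse `A = W^{-1}`, convergence info `iterations`,
#'   `converged`, `c4_signs`.
#' @export
fit_infomax_ica <- function(X, eta = 0.2, max_iter = 500L, tol = 1e-6,
                            seed = NULL) {
  if (inherits(X, "recording")) X <- X$data
  X <- as.matrix(X)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  wh <- whiten(X)
  Xw <- wh$Xw
  Q <- nrow(Xw); N <- ncol(Xw)
  W2 <- diag(Q)
  Iq <- diag(Q)
  converged <- FALSE
  c4s <- rep(1, Q)
  it <- 0L
  for (it in seq_len(max_iter)) {
    S <- W2 %*% Xw
    c4s <- apply(S, 1L, fourth_cumulant)
    sgn <- ifelse(c4s >= 0, 1, -1)
    Phi <- -(S + sgn * tanh(S))  # infomax_score, vectorised over rows
    dW <- (Iq + tcrossprod(Phi, S) / N) %*% W2
    rel <- norm(dW, "F") / norm(W2, "F")
    W2 <- W2 + eta * dW
    if (!all(is.finite(W2)))
      stop("optimization error: demixing matrix diverged at iteration ",
           it, " (reduce eta)", call. = FALSE)
    if (rel < tol) { converged <- TRUE; break }
  }
  W <- W2 %*% wh$W1
  demixing_model_time(W1 = wh$W1, W2 = W2, means = wh$means,
                      iterations = it, converged = converged,
                      c4_signs = ifelse(c4s >= 0, 1, -1))
}

# internal constructors for the two demixing-model modes --------------------

demixing_model_time <- function(W1, W2, means = NULL, ...) {
  W <- W2 %*% W1
  A <- solve(W)
  if (!all(is.finite(A)))
    stop("degeneracy error: demixing matrix is not invertible",
         call. = FALSE)
  structure(list(mode = "time", W1 = W1, W2 = W2, W = W, A = A,
                 means = means, info = list(...)),
            class = "demixing_model")
}

demixing_model_freq <- function(Wstack, fs, L, H, ...) {
  d <- dim(Wstack)
  Astack <- array(0 + 0i, c(d[1L], d[3L], d[2L]))
  for (i in seq_len(d[1L])) {
    Ai <- tryCatch(solve(Wstack[i, , ]), error = function(e) NULL)
    if (is.null(Ai) || !all(is.finite(Ai)))
      stop("inversion error: demixing matrix singular at bin ", i,
           call. = FALSE)
    Astack[i, , ] <- Ai
  }
  structure(list(mode = "frequency", Wstack = Wstack, Astack = Astack,
                 fs = fs, L = L, H = H, info = list(...)),
            class = "demixing_model")
}

#' @export
print.demixing_model <- function(x, ...) {
  if (x$mode == "time") {
    cat("<demixing_model> time mode, ", nrow(x$W), " sources\n", sep = "")
  } else {
    d <- dim(x$Wstack)
    cat("<demixing_model> frequency mode, ", d[2L], " sources x ", d[1L],
        " bins\n", sep = "")
  }
  invisible(x)
}

#' Apply a time-mode demixing model
#'
#' @param model a time-mode `demixing_model`.
#' @param X channels x samples matrix.
#' @return estimated sources, `W %*% X`.
#' @export
apply_demixing <- function(model, X) {
  stopifnot(inherits(model, "demixing_model"))
  if (model$mode != "time")
    stop("shape error: apply_demixing needs a time-mode model",
         call. = FALSE)
  X <- as.matrix(X)
  if (nrow(X) != ncol(model$W))
    stop("shape error: model expects ", ncol(model$W), " channels, got ",
         nrow(X), call. = FALSE)
  model$W %*% X
}

#' Apply the cached mixing (inverse demixing) of a time-mode model
#'
#' @param model a time-mode `demixing_model`.
#' @param S sources x samples matrix.
#' @return remixed channels, `A %*% S`.
#' @export
apply_mixing <- function(model, S) {
  stopifnot(inherits(model, "demixing_model"))
  if (model$mode != "time")
    stop("shape error: apply_mixing needs a time-mode model", call. = FALSE)
  S <- as.matrix(S)
  if (nrow(S) != nrow(model$A))
    stop("shape error: model expects ", nrow(model$A), " sources, got ",
         nrow(S), call. = FALSE)
  model$A %*% S
}
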