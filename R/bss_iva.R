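#' @title Independent vector analysis
#' @name bss_iva
#' @description Frequency-domain determined BSS over STFT tensors. A
#'   spherical multivariate super-Gaussian source prior couples all
#'   frequency bins of one source, so the natural-gradient updates align
#'   source order across bins and the classic per-bin permutation
#'   ambiguity of bin-wise ICA is avoided.
NULL

#' IVA multivariate score function
#'
#' For one source and frame with per-bin values `s = (s_1, ..., s_I)`,
#' returns `s_i / sqrt(sum_i' |s_i'|^2)` — the score of the spherical
#' super-Gaussian source prior. The all-zero vector maps to all zeros
#' (defined limit).
#'
#' @param svec complex (or numeric) vector of per-bin values.
#' @return complex vector of the same length.
#' @export
iva_score <- function(svec) {
  nrm <- sqrt(sum(Mod(svec)^2))
  if (nrm == 0) return(svec * 0)
  svec / nrm
}

# empirical IVA cost: negative log-likelihood of the spherical Laplacian
# prior plus the demixing log-determinant terms, up to constants
iva_cost <- function(Wstack, Y) {
  I <- dim(Y)[1L]; J <- dim(Y)[2L]; Q <- dim(Y)[3L]
  nrm <- sqrt(apply(Mod(Y)^2, c(2L, 3L), sum))  # J x Q
  ld <- 0
  for (i in seq_len(I)) ld <- ld + sum(log(La.svd(Wstack[i, , ])$d))
  sum(nrm) - J * ld
}

#' Fit natural-gradient IVA
#'
#' Each bin is whitened first; the per-bin square demixing matrices (all
#' initialised at identity) are then updated jointly by
#' `W_i <- W_i + eta * (I - E_j[phi_i(s_j) s_{ij}^H]) W_i`, where the score
#' `phi` couples all bins of a source ([iva_score()]). Iteration stops when
#' the mean relative update norm falls below `tol` or after `max_iter`
#' steps.
#'
#' @param spec a `spectrogram` (see [stft()]) of the mixture.
#' @param eta learning rate.
#' @param max_iter maximum iterations.
#' @param tol convergence threshold on the mean relative Frobenius update.
#' @param seed optional seed, recorded for provenance (the fit itself is
#'   deterministic).
#' @return A frequency-mode `demixing_model` whose `Wstack[i, , ]` maps
#'   observed bin-i coefficients to sources; `info` carries the start/end
#'   cost and iteration count.
#' @export
fit_iva <- function(spec, eta = 0.1, max_iter = 500L, tol = 1e-6,
                    seed = NULL) {
  stopifnot(inherits(spec, "spectrogram"))
  X <- spec$tensor
  P <- dim(X)[1L]; I <- dim(X)[2L]; J <- dim(X)[3L]
  Q <- P
  if (J <= P)
    stop("precondition error: need more frames than channels (J=", J,
         ", P=", P, ")", call. = FALSE)
  # per-bin whitening
  Wh <- array(0 + 0i, c(I, Q, P))
  Xw <- array(0 + 0i, c(P, I, J))
  for (i in seq_len(I)) {
    Xi <- X[, i, , drop = TRUE]
    if (P == 1L) Xi <- matrix(Xi, 1L)
    C <- Xi %*% Conj(t(Xi)) / J
    e <- eigen(C, symmetric = TRUE)
    Wh[i, , ] <- diag(1 / sqrt(pmax(Re(e$values), 1e-12)), Q) %*%
      Conj(t(e$vectors))
    Xw[, i, ] <- Wh[i, , ] %*% Xi
  }
  W <- array(0 + 0i, c(I, Q, Q))
  for (i in seq_len(I)) W[i, , ] <- diag(Q)
  Y <- Xw
  Wtot0 <- W
  for (i in seq_len(I)) Wtot0[i, , ] <- W[i, , ] %*% Wh[i, , ]
  cost0 <- iva_cost(Wtot0, aperm(Y, c(2L, 3L, 1L)))
  Iq <- diag(Q)
  it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    nrm <- sqrt(apply(Mod(Y)^2, c(1L, 3L), sum))  # Q x J, per-source norms
    nrm[nrm == 0] <- 1  # defined limit: zero vector -> zero score
    rel <- 0
    for (i in seq_len(I)) {
      Yi <- Y[, i, , drop = TRUE]
      if (Q == 1L) Yi <- matrix(Yi, 1L)
      Phi <- Yi / nrm
      G <- Iq - (Phi %*% Conj(t(Yi))) / J
      dW <- G %*% W[i, , ]
      if (!all(is.finite(dW)))
        stop("optimization error: non-finite update at bin ", i,
             ", iteration ", it, call. = FALSE)
      W[i, , ] <- W[i, , ] + eta * dW
      Y[, i, ] <- W[i, , ] %*% Xw[, i, ]
      rel <- rel + frob(dW) / max(frob(W[i, , ]), 1e-12)
    }
    if (rel / I < tol) { converged <- TRUE; break }
  }
  Wtot <- array(0 + 0i, c(I, Q, P))
  for (i in seq_len(I)) Wtot[i, , ] <- W[i, , ] %*% Wh[i, , ]
  cost1 <- iva_cost(Wtot, aperm(Y, c(2L, 3L, 1L)))
  demixing_model_freq(Wtot, fs = spec$fs, L = spec$L, H = spec$H,
                      iterations = it, converged = converged,
                      cost_start = cost0, cost_end = cost1)
}

#' Apply a frequency-mode demixing model bin-wise
#'
#' @param model a frequency-mode `demixing_model`.
#' @param spec mixture `spectrogram` with matching bin count.
#' @return a `spectrogram` of estimated sources (`y_ij = W_i x_ij`).
#' @export
apply_demixing_freq <- function(model, spec) {
  stopifnot(inherits(model, "demixing_model"),
            inherits(spec, "spectrogram"))
  if (model$mode != "frequency")
    stop("shape error: frequency-mode model required", call. = FALSE)
  d <- dim(spec$tensor)
  dw <- dim(model$Wstack)
  if (dw[1L] != d[2L] || dw[3L] != d[1L])
    stop("shape error: model is ", dw[1L], " bins x ", dw[3L],
         " channels; spectrogram is ", d[2L], " x ", d[1L], call. = FALSE)
  out <- array(0 + 0i, c(dw[2L], d[2L], d[3L]))
  for (i in seq_len(d[2L])) {
    Xi <- spec$tensor[, i, , drop = TRUE]
    if (d[1L] == 1L) Xi <- matrix(Xi, 1L)
    out[, i, ] <- model$Wstack[i, , ] %*% Xi
  }
  structure(list(tensor = out, fs = spec$fs, L = spec$L, H = spec$H,
                 window = spec$window), class = "spectrogram")
}

# Frobenius norm valid for complex matrices (base::norm discards Im)
frob <- function(M) sqrt(sum(Mod(M)^2))
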