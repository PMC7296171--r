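# shared fixtures, all generated in code

# a tiny deterministic recording
tiny_recording <- function(P = 3, N = 400, fs = 100, seed = 42) {
  set.seed(seed)
  recording(matrix(rnorm(P * N), P, N), fs = fs)
}

# 3x3 mixture of low-rank broadband sources (the regime the frequency-
# domain methods are designed for), with ground truth attached
lowrank_mixture <- function(seed, duration = 60, fs = 100, Q = 3,
                            noise_sd = 0.01) {
  src <- make_sources(rep(list("lowrank"), Q), fs, duration,
                      seed = seed * 101)
  set.seed(seed)
  A <- matrix(rnorm(Q * Q), Q, Q)
  while (kappa(A) > 20) A <- matrix(rnorm(Q * Q), Q, Q)
  X <- A %*% src$S + noise_sd * matrix(rnorm(Q * duration * fs), Q)
  list(S = src$S, A = A, rec = recording(X, fs))
}

# aligned absolute correlations between an ILRMA-style frequency-domain
# fit and ground-truth sources: per-source projection back at every
# channel, best channel per (estimate, truth) pair, optimal assignment
aligned_freq_correlation <- function(model, Y, S) {
  n <- ncol(S)
  img <- source_images(model, Y, out_length = n)
  Q <- dim(img)[1L]; P <- dim(img)[2L]
  cm <- matrix(0, Q, nrow(S))
  for (q in seq_len(Q)) for (r in seq_len(nrow(S)))
    cm[q, r] <- max(vapply(seq_len(P), function(p)
      abs(cor(img[q, p, ], S[r, ])), numeric(1)))
  perms <- eegbss:::all_permutations(Q)
  tot <- apply(perms, 1L, function(p) sum(cm[cbind(seq_len(Q), p)]))
  cm[cbind(seq_len(Q), perms[which.max(tot), ])]
}
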