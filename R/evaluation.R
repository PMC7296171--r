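#' @title Separation and identification quality metrics
#' @name evaluation
#' @description Permutation-aligned correlation against ground-truth
#'   sources, the Amari index of a global (demixing x mixing) matrix, the
#'   percentage-accuracy metric, canonical-correlation SSVEP frequency
#'   identification, and summaries of the packaged per-subject
#'   artifact-epoch count table.
NULL

# all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  dimnames(out) <- NULL
  out
}

#' Align estimated sources to ground truth and correlate
#'
#' Separation has inherent permutation and sign/scale ambiguity. This
#' finds the one-to-one assignment maximising the total absolute Pearson
#' correlation (exhaustive for up to 8 sources, greedy beyond) and
#' returns it with the matched `|r|` values.
#'
#' @param est Q x N matrix of estimated sources.
#' @param truth Q x N matrix of true sources.
#' @return list with `permutation` (truth index for each estimated row)
#'   and `correlation` (matched absolute correlations).
#' @export
align_and_correlate <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth)))
    stop("shape error: est and truth must have equal dimensions",
         call. = FALSE)
  Q <- nrow(est)
  sds <- c(apply(est, 1L, stats::sd), apply(truth, 1L, stats::sd))
  if (any(sds == 0))
    stop("degeneracy error: constant row has undefined correlation",
         call. = FALSE)
  cm <- abs(stats::cor(t(est), t(truth)))
  if (Q <= 8L) {
    perms <- all_permutations(Q)
    tot <- apply(perms, 1L, function(p) sum(cm[cbind(seq_len(Q), p)]))
    best <- perms[which.max(tot), ]
  } else {
    best <- integer(Q)
    free <- seq_len(Q)
    for (q in order(apply(cm, 1L, max), decreasing = TRUE)) {
      pick <- free[which.max(cm[q, free])]
      best[q] <- pick
      free <- setdiff(free, pick)
    }
  }
  list(permutation = best,
       correlation = cm[cbind(seq_len(Q), best)])
}

#' Amari index of a global matrix
#'
#' For `G = W A`, `(1/2Q) sum_i (sum_j |g_ij| / max_j |g_ij| - 1) +
#' (1/2Q) sum_j (sum_i |g_ij| / max_i |g_ij| - 1)`: zero exactly when G is
#' a scaled permutation (perfect separation), invariant to row/column
#' scaling and permutation.
#'
#' @param G square numeric matrix.
#' @return nonnegative scalar.
#' @export
amari_index <- function(G) {
  G <- abs(as.matrix(G))
  if (any(rowSums(G) == 0) || any(colSums(G) == 0))
    stop("degeneracy error: zero row or column", call. = FALSE)
  Q <- nrow(G)
  a <- sum(rowSums(G) / apply(G, 1L, max) - 1)
  b <- sum(colSums(G) / apply(G, 2L, max) - 1)
  (a + b) / (2 * Q)
}

#' Classification accuracy in percent
#'
#' @param n_correct number of correct predictions.
#' @param n_total total number of predictions (>= 1).
#' @return `100 * n_correct / n_total`.
#' @export
accuracy <- function(n_correct, n_total) {
  if (n_total < 1)
    stop("undefined-metric error: accuracy needs at least one epoch",
         call. = FALSE)
  if (n_correct < 0 || n_correct > n_total)
    stop("accuracy needs 0 <= n_correct <= n_total", call. = FALSE)
  100 * n_correct / n_total
}

#' Identify an SSVEP target frequency by canonical correlation
#'
#' For each candidate frequency a sinusoidal template (sine and cosine at
#' harmonics 1..`harmonics`) is built and the first canonical correlation
#' with the multichannel epoch is computed; the candidate with the largest
#' correlation wins.
#'
#' @param epoch channels x samples matrix (>= 2 channels, >= 1 s).
#' @param fs sampling rate in Hz.
#' @param freqs candidate frequencies in Hz (defaults to the four
#'   stimulation frequencies 5.45, 6.67, 8.57, 12).
#' @param harmonics number of harmonics in the template (default 2).
#' @return index into `freqs` of the identified frequency, with the
#'   per-candidate correlations as attribute `"rho"`.
#' @export
cca_identify <- function(epoch, fs, freqs = ssvep_frequencies,
                         harmonics = 2L) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n < fs) stop("length error: epoch must be at least 1 s",
                   call. = FALSE)
  if (nrow(epoch) < 2L) stop("length error: need >= 2 channels",
                             call. = FALSE)
  t_sec <- (0:(n - 1L)) / fs
  rho <- vapply(freqs, function(f) {
    tmpl <- do.call(cbind, lapply(seq_len(harmonics), function(h)
      cbind(sin(2 * pi * f * h * t_sec), cos(2 * pi * f * h * t_sec))))
    if (qr(tmpl)$rank < ncol(tmpl))
      stop("template error: rank-deficient template at ", f, " Hz ",
           "(harmonic above Nyquist?)", call. = FALSE)
    stats::cancor(t(epoch), tmpl)$cor[1L]
  }, numeric(1L))
  structure(which.max(rho), rho = rho)
}

#' Per-subject artifact-contaminated epoch counts
#'
#' Loads the packaged table of artifact-contaminated epoch counts per
#' subject (54 subjects), paradigm (MI, ERP, SSVEP), session (1, 2) and
#' phase (train, test). ERP test columns additionally carry the number of
#' affected characters (`erp_s*_test_chars`).
#'
#' @return data.frame with a `subject` column and one column per
#'   (paradigm, session, phase).
#' @export
epoch_count_table <- function() {
  path <- system.file("extdata", "artifact_epoch_counts.tsv",
                      package = "eegbss")
  utils::read.delim(path, check.names = FALSE)
}

#' Mean and standard deviation of an epoch-count column
#'
#' @param table data.frame from [epoch_count_table()] (or of the same
#'   shape).
#' @param paradigm `"mi"`, `"erp"` or `"ssvep"`.
#' @param session 1 or 2.
#' @param phase `"train"` or `"test"`.
#' @return list with `mean` and `sd` (sample standard deviation,
#'   n-1 denominator) of the per-subject counts.
#' @export
summarize_epoch_counts <- function(table, paradigm, session, phase) {
  col <- paste0(tolower(paradigm), "_s", session, "_", tolower(phase))
  if (!col %in% names(table))
    stop("key error: no column '", col, "' in the epoch-count table",
         call. = FALSE)
  v <- table[[col]]
  if (!length(v)) stop("key error: empty column '", col, "'",
                       call. = FALSE)
  list(mean = mean(v), sd = stats::sd(v))
}
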