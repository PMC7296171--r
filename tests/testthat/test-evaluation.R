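test_that("alignment recovers permutations and signs", {
  set.seed(20)
  S <- matrix(rnorm(3 * 500), 3)
  al <- align_and_correlate(S, S)
  expect_equal(al$permutation, 1:3)
  expect_equal(al$correlation, rep(1, 3), tolerance = 1e-12)

  est <- S[c(2, 3, 1), ]
  est[2, ] <- -est[2, ]
  al <- align_and_correlate(est, S)
  expect_equal(al$permutation, c(2, 3, 1))
  expect_equal(al$correlation, rep(1, 3), tolerance = 1e-12)

  noisy <- S + matrix(rnorm(length(S), 0, sqrt(0.1)), 3)  # SNR 10
  al <- align_and_correlate(noisy, S)
  expect_true(all(al$correlation > 0.9))

  expect_error(align_and_correlate(rbind(S, 0), rbind(S, 0)),
               "degeneracy")
  expect_error(align_and_correlate(S, S[, 1:10]), "shape")
})

test_that("the Amari index vanishes exactly on scaled permutations", {
  expect_equal(amari_index(diag(4)), 0)
  P <- diag(3)[c(2, 3, 1), ] %*% diag(c(2, -0.5, 10))
  expect_equal(amari_index(P), 0)
  expect_equal(amari_index(matrix(1, 2, 2)), 1)
  expect_error(amari_index(rbind(c(1, 1), c(0, 0))), "degeneracy")

  # invariance under row/column permutation and global scaling
  set.seed(21)
  G <- matrix(rnorm(16), 4)
  Pm <- diag(4)[sample(4), ]
  expect_equal(amari_index(Pm %*% G %*% t(Pm)), amari_index(G),
               tolerance = 1e-12)
  expect_equal(amari_index(-3.7 * G), amari_index(G), tolerance = 1e-12)
})

test_that("accuracy is an exact percentage with guarded degenerate input", {
  expect_equal(accuracy(5, 10), 50)
  expect_equal(accuracy(10, 10), 100)
  expect_equal(accuracy(0, 7), 0)
  expect_error(accuracy(0, 0), "undefined-metric")
  expect_error(accuracy(5, 3), "n_correct")
})

test_that("CCA identification finds the stimulation frequency", {
  fs <- 100
  t_sec <- (0:199) / fs  # the paradigm's 2-s epochs
  set.seed(22)
  mix <- matrix(rnorm(3 * 2), 3, 2)
  base <- rbind(sin(2 * pi * 12 * t_sec), cos(2 * pi * 12 * t_sec))
  epoch <- mix %*% base + 0.05 * matrix(rnorm(3 * 200), 3)
  id <- cca_identify(epoch, fs)
  expect_equal(id[[1]], 4L)  # 12 Hz is the 4th default frequency
  expect_length(attr(id, "rho"), 4L)

  # invariance to invertible channel mixing
  M <- matrix(c(2, 1, 0, 1, 3, 0.5, 0, 1, 1), 3)
  expect_equal(cca_identify(M %*% epoch, fs)[[1]], 4L)
})

test_that("the packaged epoch-count table reproduces the printed summaries", {
  tab <- epoch_count_table()
  expect_equal(nrow(tab), 54L)
  expect_equal(round(summarize_epoch_counts(tab, "mi", 1, "train")$mean, 2),
               6.11)
  expect_equal(round(summarize_epoch_counts(tab, "mi", 2, "test")$mean, 2),
               3.81)
  expect_equal(signif(summarize_epoch_counts(tab, "erp", 1, "train")$mean, 3),
               152)
  expect_equal(round(summarize_epoch_counts(tab, "ssvep", 2, "test")$mean, 2),
               5.30)
  expect_error(summarize_epoch_counts(tab, "mi", 3, "train"), "key error")

  zero <- data.frame(mi_s1_train = rep(0, 10))
  s <- summarize_epoch_counts(zero, "mi", 1, "train")
  expect_equal(c(s$mean, s$sd), c(0, 0))
})
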