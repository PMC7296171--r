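test_that("band collapse averages the demixing stack over selected bins", {
  I <- 51; Q <- 3
  M <- matrix(complex(real = rnorm(Q * Q), imaginary = rnorm(Q * Q)), Q, Q)
  Wstack <- array(0 + 0i, c(I, Q, Q))
  for (i in seq_len(I)) Wstack[i, , ] <- M
  expect_equal(collapse_band(Wstack, fs = 100, band = c(8, 30), L = 100),
               Re(M))
  # 1-Hz bins: [8, 30] inclusive has 23 bins -> averaging by 23
  W2 <- Wstack
  W2[9:31, , ] <- 2 * W2[9:31, , ]  # bins at 8..30 Hz
  expect_equal(collapse_band(W2, fs = 100, band = c(8, 30), L = 100),
               2 * Re(M))
  expect_error(collapse_band(Wstack, fs = 100, band = c(60, 70), L = 100),
               "band error")
})

test_that("topographies obey projection geometry and the 0.99 scaling", {
  lay <- layout_1020(c("Fp1", "Fp2", "Cz", "Pz", "O1", "O2"))
  img <- topography(rep(1, 6), lay)
  inside <- img[img != 0]
  expect_true(all(abs(inside - 0.99) < 1e-12))

  # weight on the most frontal electrodes -> argmax in the top third
  img <- topography(c(1, 1, 0, 0, 0, 0), lay)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_lte(peak["row"], nrow(img) / 3)
  expect_equal(max(abs(img)), 0.99)

  expect_true(all(topography(rep(0, 6), lay) == 0))
  lay3 <- channel_layout(c("a", "b"), rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_error(topography(c(1, 1), lay3), "geometry")
})

test_that("the median PSD peaks correctly and scales to 0.99", {
  t_sec <- (0:999) / 100
  p <- median_psd(sin(2 * pi * 10 * t_sec), fs = 100)
  expect_equal(attr(p, "freq")[which.max(p)], 10)
  set.seed(11)
  p <- median_psd(rnorm(1000), fs = 100)
  expect_equal(max(abs(p)), 0.99)
  expect_equal(attr(p, "freq"), 1:49)
  expect_error(median_psd(rnorm(150), fs = 100), "length error")
})

test_that("the autocorrelation is 0.99 at lag zero and shows periodicity", {
  set.seed(12)
  a <- autocorr(rnorm(1000), fs = 100)
  expect_identical(a[1], 0.99)
  expect_lt(max(abs(a[-1])), 0.1)
  t_sec <- (0:2999) / 100
  a <- autocorr(sin(2 * pi * 10 * t_sec), fs = 100)
  # period 0.1 s = lag 10 samples -> local maximum at index 11
  expect_gt(a[11], a[10]); expect_gt(a[11], a[12])
  expect_error(autocorr(rep(1, 500), fs = 100), "degeneracy")
})

test_that("the heuristic classifier labels the three fixture components", {
  fs <- 100
  lay <- layout_1020(c("Fp1", "Fp2", "Cz", "Pz", "O1", "O2"))
  n <- 30 * fs
  set.seed(13)
  # blink: slow frontal pulse train
  blink <- make_sources(list("eye-blink"), fs, 30, seed = 1)$S[1, ]
  f_eye <- ic_features(blink, c(1, 0.9, 0.2, 0.1, 0.05, 0.05), lay, fs)
  # muscle: high-frequency bursts
  musc <- make_sources(list("muscle-burst"), fs, 30, seed = 2)$S[1, ]
  f_mus <- ic_features(musc, c(0.2, 0.2, 0.5, 0.3, 0.4, 0.6), lay, fs)
  # brain: 10-Hz posterior oscillation
  osc <- make_sources(list(list(kind = "neuronal-osc", freq = 10)),
                      fs, 30, seed = 3)$S[1, ]
  f_brain <- ic_features(osc, c(0.05, 0.05, 0.3, 0.6, 1, 0.9), lay, fs)

  res <- classify_components(list(f_eye, f_mus, f_brain))
  expect_equal(res$label, c("eye", "muscle", "brain"))
  expect_true(all(res$label %in% ic_labels))
  conf <- as.matrix(res[, ic_labels])
  expect_equal(unname(rowSums(conf)), rep(1, 3), tolerance = 1e-12)
})

test_that("feature scaling contracts hold for arbitrary components", {
  fs <- 100
  lay <- layout_1020(c("Fp1", "Fp2", "Cz", "Pz", "O1", "O2"))
  set.seed(14)
  for (k in 1:5) {
    f <- ic_features(rnorm(500), rnorm(6), lay, fs)
    expect_equal(max(abs(f$topo)), 0.99)
    expect_equal(max(abs(f$psd)), 0.99)
    expect_identical(f$acf[1], 0.99)
  }
})

test_that("a classifier emitting unknown labels violates the contract", {
  fs <- 100
  lay <- layout_1020(c("Fp1", "Fp2", "Cz", "Pz", "O1", "O2"))
  f <- ic_features(rnorm(500), rnorm(6), lay, fs)
  bad <- function(features) c(ghost = 1)
  expect_error(classify_components(list(f), bad), "contract")
})
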