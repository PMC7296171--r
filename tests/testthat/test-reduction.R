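test_that("time-domain removal is exact for the trivial drop sets", {
  set.seed(30)
  X <- matrix(rnorm(3 * 4000), 3)
  m <- fit_infomax_ica(X, max_iter = 50)
  expect_lt(max(abs(remove_components_time(X, m, integer()) - X)), 1e-10)
  expect_true(all(abs(remove_components_time(X, m, 1:3)) < 1e-10))
  # dropping component q leaves its demixed row identically zero
  clean <- remove_components_time(X, m, 2L)
  expect_lt(max(abs((m$W %*% clean)[2, ])), 1e-10)
  expect_error(remove_components_time(X, m, 7L), "index")
})

test_that("frequency-domain removal matches the plain round trip", {
  mx <- lowrank_mixture(seed = 3, duration = 20)
  sp <- stft(mx$rec)
  fit <- fit_ilrma(sp, iters = 30, seed = 1)
  n <- ncol(mx$rec$data)
  rt <- istft(sp, n)
  clean0 <- remove_components_freq(sp, fit$model, integer(), n)
  expect_lt(max(abs(clean0 - rt)), 1e-8)
  expect_true(all(remove_components_freq(sp, fit$model, 1:3, n) == 0))
})

test_that("the fixed reduction operator is linear and idempotent", {
  mx <- lowrank_mixture(seed = 4, duration = 20)
  sp <- stft(mx$rec)
  fit <- fit_ilrma(sp, iters = 30, seed = 1)
  n <- 1500
  X1 <- mx$rec$data
  set.seed(31)
  X2 <- matrix(rnorm(length(X1)), nrow(X1))
  red <- function(X) remove_components_freq(stft(X, fs = 100), fit$model,
                                            2L, n)
  lin <- red(2 * X1 + 0.5 * X2)
  expect_equal(lin, 2 * red(X1) + 0.5 * red(X2), tolerance = 1e-8)

  # with a bin-constant demixing stack the operator is a pure spatial
  # filter, so applying it twice is exactly applying it once
  I <- dim(sp$tensor)[2]
  set.seed(32)
  W0 <- matrix(rnorm(9), 3, 3)
  Wstack <- array(0 + 0i, c(I, 3, 3))
  for (i in seq_len(I)) Wstack[i, , ] <- W0
  m0 <- eegbss:::demixing_model_freq(Wstack, fs = 100, L = sp$L, H = sp$H)
  red0 <- function(X) remove_components_freq(stft(X, fs = 100), m0, 2L, n)
  once <- red0(X1)
  expect_equal(red0(once), once, tolerance = 1e-8)

  # a fitted (bin-varying) stack re-projects an inconsistent spectrogram,
  # so idempotence is only approximate
  once <- red(X1)
  twice <- remove_components_freq(stft(once, fs = 100), fit$model, 2L, n)
  expect_lt(sqrt(mean((twice - once)^2)) / sd(once), 0.15)
})

test_that("removing the blink component moves epochs toward the clean EEG", {
  scene <- default_scene(seed = 5)
  rec <- simulate_recording(scene)
  # ground-truth artifact-free mixture: zero the blink and muscle sources
  Sclean <- scene$sources$S
  Sclean[scene$sources$kinds %in% c("eye-blink", "muscle-burst"), ] <- 0
  Xclean <- scene$A %*% Sclean
  sp <- stft(rec)
  fit <- fit_ilrma(sp, iters = 100, seed = 1)
  # find the estimated components matching the blink and muscle truths
  img <- source_images(fit$model, fit$Y, ncol(rec$data))
  match_to <- function(truth) which.max(sapply(seq_len(4), function(q)
    max(sapply(seq_len(4), function(p) abs(cor(img[q, p, ], truth))))))
  drop <- unique(c(
    match_to(scene$sources$S[scene$sources$kinds == "eye-blink", ]),
    match_to(scene$sources$S[scene$sources$kinds == "muscle-burst", ])))
  clean <- remove_components_freq(sp, fit$model, drop, ncol(rec$data))
  n <- ncol(clean)
  before <- cor(as.vector(rec$data[, 1:n]), as.vector(Xclean[, 1:n]))
  after <- cor(as.vector(clean), as.vector(Xclean[, 1:n]))
  expect_gt(after, before)
})

test_that("the pipeline is a no-op when nothing is labelled artifactual", {
  scene <- default_scene(seed = 6, duration = 20)
  rec <- simulate_recording(scene)
  eps <- segment_epochs(rec, seq(1, 1801, by = 200), 200)
  all_brain <- function(features)
    stats::setNames(c(1, rep(0, 6)), eegbss::ic_labels)
  res <- reduce_pipeline(eps, eps, method = "ilrma", iters = 30,
                         classifier = all_brain, seed = 1)
  expect_length(res$report$dropped, 0L)
  expect_equal(res$epochs$epochs, eps$epochs, tolerance = 1e-7)
  expect_length(res$report$cost_trace, 31L)
})

test_that("pipeline errors carry the failing stage name", {
  scene <- default_scene(seed = 7, duration = 20)
  rec <- simulate_recording(scene)
  eps <- segment_epochs(rec, seq(1, 1801, by = 200), 200)
  bad <- eps
  bad$layout <- NULL
  expect_error(reduce_pipeline(bad, bad, method = "ilrma"),
               "stage identify")
  short <- segment_epochs(rec, 1, 150)  # J = 2 frames per epoch, too few
  expect_error(reduce_pipeline(short, short, method = "iva", seed = 1),
               "stage separate")
})
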