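test_that("the eyeblink source blinks about 20 times per minute", {
  src <- make_sources(list("eye-blink"), fs = 100, duration = 60, seed = 1)
  expect_length(src$annotations[[1]]$event_times, 20L)
  # interval 3 s, deterministic without jitter
  expect_equal(diff(src$annotations[[1]]$event_times), rep(3, 19))
})

test_that("sources are reproducible bit for bit from the seed", {
  kinds <- list("eye-blink", "muscle-burst", "lowrank",
                list(kind = "neuronal-osc", freq = 10))
  a <- make_sources(kinds, 100, 10, seed = 7)
  b <- make_sources(kinds, 100, 10, seed = 7)
  expect_identical(a$S, b$S)
  c <- make_sources(kinds, 100, 10, seed = 8)
  expect_false(identical(a$S, c$S))
})

test_that("the SSVEP source peaks at its stimulation frequency", {
  src <- make_sources(list(list(kind = "ssvep", freq = 12)), 100, 20,
                      seed = 2)
  p <- median_psd(src$S[1, ], 100)
  expect_equal(attr(p, "freq")[which.max(p)], 12)
  expect_error(make_sources(list(list(kind = "ssvep", freq = 11)),
                            100, 10, seed = 1), "spec error")
  expect_error(make_sources(list("nonsense"), 100, 10, seed = 1),
               "spec error")
  expect_error(make_sources(list("lowrank"), 100, 1, seed = 1),
               "duration")
})

test_that("the mixing matrix decays with distance and stays conditioned", {
  lay <- layout_1020(c("Fp1", "Fp2", "Cz", "Oz"))
  # a source exactly at an electrode: that electrode gets the max gain
  locs <- rbind(lay$positions["Oz", ], c(0, 0.9, 0.3))
  for (sd in 1:5) {
    A <- make_mixing(lay, locs, seed = sd)
    expect_equal(which.max(A[, 1]), 4L)  # Oz row
    expect_lte(kappa(A, exact = TRUE), 100)
  }
  expect_error(make_mixing(lay, matrix(0, 5, 3), seed = 1), "generation")
})

test_that("simulate_recording realises X = A S + D", {
  scene <- default_scene(seed = 3, duration = 10)
  scene$noise_sd <- 0
  rec <- simulate_recording(scene)
  expect_equal(unname(rec$data), scene$A %*% scene$sources$S,
               tolerance = 0)

  # doubling a source doubles its contribution (linearity)
  scene2 <- scene
  scene2$sources$S[2, ] <- 2 * scene2$sources$S[2, ]
  diffX <- unname(simulate_recording(scene2)$data - rec$data)
  expect_equal(diffX, outer(scene$A[, 2], scene$sources$S[2, ]),
               tolerance = 1e-12)

  # empirical noise variance tracks noise_sd^2
  src <- make_sources(list("lowrank", "lowrank"), 100, 1000, seed = 4)
  A <- diag(2)
  scene3 <- make_scene(src, A, layout_1020(c("Fp1", "Oz")), 100,
                       noise_sd = 0.5, seed = 5)
  D <- simulate_recording(scene3)$data - src$S
  expect_lt(abs(mean(D^2) - 0.25) / 0.25, 0.05)
})

test_that("the default scene is the determined 4x4 study configuration", {
  scene <- default_scene(seed = 1)
  expect_equal(dim(scene$A), c(4L, 4L))
  expect_equal(scene$sources$kinds,
               c("neuronal-osc", "neuronal-osc", "eye-blink",
                 "muscle-burst"))
  expect_equal(ncol(scene$sources$S), 6000L)
  expect_lte(kappa(scene$A, exact = TRUE), 100)
  # blink column projects mainly to the frontal electrodes
  blink_col <- scene$A[, 3]
  expect_true(all(blink_col[1:2] > blink_col[3:4]))
})
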