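test_that("asymmetry index reproduces its defining limit cases", {
  tt <- (0:499) / 500
  alpha <- sin(2 * pi * 10 * tt)

  sym <- matrix(rep(alpha, 6), 6, byrow = TRUE,
    dimnames = list(aai_channels, NULL))
  expect_equal(compute_aai(sym), 0)

  right_only <- sym
  right_only[c("C3", "CP3", "CP5"), ] <- 0
  expect_equal(compute_aai(right_only), 1, tolerance = 1e-9)

  left_only <- sym
  left_only[c("C4", "CP4", "CP6"), ] <- 0
  expect_equal(compute_aai(left_only), -1, tolerance = 1e-9)

  # right power twice the left: (2 - 1) / (2 + 1)
  ratio <- sym
  ratio[c("C4", "CP4", "CP6"), ] <- sqrt(2) * ratio[c("C4", "CP4", "CP6"), ]
  expect_equal(compute_aai(ratio), 1 / 3, tolerance = 1e-6)
})

test_that("asymmetry index is scale invariant and flags zero power", {
  set.seed(41)
  for (i in 1:5) {
    w <- matrix(rnorm(6 * 500), 6, dimnames = list(aai_channels, NULL))
    expect_equal(compute_aai(w * runif(1, 0.1, 40)), compute_aai(w),
      tolerance = 1e-12)
  }
  flat <- matrix(1, 6, 500, dimnames = list(aai_channels, NULL))
  expect_warning(out <- compute_aai(flat), "undefined")
  expect_true(is.na(out))
})

test_that("asymmetry index validates montage and window duration", {
  w <- matrix(rnorm(4 * 500), 4,
    dimnames = list(c("C3", "CP3", "C4", "CP4"), NULL))
  expect_error(compute_aai(w), "required channels")
  w2 <- matrix(rnorm(6 * 400), 6, dimnames = list(aai_channels, NULL))
  expect_error(compute_aai(w2), "1,000 ms")
})

test_that("temporal smoothing matches 1 ms trapezoid quadrature", {
  expect_equal(smooth_aai(rep(0.4, 50))$faai, rep(0.4, 50))

  step <- c(rep(0, 31), rep(1, 15)) # step within the trailing window
  s <- smooth_aai(step)
  expect_equal(s$faai[46], oracle_smooth_trapezoid(step, 46),
    tolerance = 1e-4)

  set.seed(7)
  x <- runif(60, -1, 1)
  s <- smooth_aai(x)
  for (i in c(1, 2, 5, 17, 31, 60)) {
    expect_equal(s$faai[i], oracle_smooth_trapezoid(x, i), tolerance = 1e-4)
  }
  expect_identical(s$faai[1], x[1]) # degenerate window: raw sample
})

test_that("temporal smoothing is shift equivariant in the interior", {
  set.seed(8)
  x <- runif(80, -1, 1)
  k <- 10L
  full <- smooth_aai(x)$faai
  shifted <- smooth_aai(x[(k + 1):80])$faai
  # indices with a full 3 s history in both series
  idx <- 31:length(shifted)
  expect_equal(shifted[idx], full[idx + k], tolerance = 1e-12)
})

test_that("visibility map reproduces the piecewise definition", {
  expect_equal(visibility(0.7, "ART"), 1)
  expect_equal(visibility(-0.7, "ART"), 0)
  expect_equal(visibility(0, "ART"), 0.2)
  expect_equal(visibility(0, "ALT"), 0.2)
  expect_equal(visibility(-0.3, "ALT"), 0.6)
  expect_equal(visibility(-0.3, "ART"), 0.1)
  expect_equal(visibility(0.3, "ART"), 0.2 + 4 / 3 * 0.3)
  expect_equal(visibility(0.3, "ALT"), 0.2 - 1 / 3 * 0.3)
  expect_equal(visibility(-0.7, "ALT"), 1)
  expect_equal(visibility(0.7, "ALT"), 0)

  grid <- seq(-1, 1, by = 0.01)
  expect_true(all(diff(visibility(grid, "ART")) >= 0))
  expect_true(all(diff(visibility(grid, "ALT")) <= 0))
  expect_true(all(visibility(grid, "ART") >= 0 & visibility(grid, "ART") <= 1))
})

test_that("trial reward follows the capped linear schedule with bonus", {
  expect_equal(compute_reward(-0.2, "ART"), 0)
  expect_equal(compute_reward(0.7, "ART"), 0.50)
  expect_equal(compute_reward(-0.3, "ALT"), 0.125)
  expect_equal(compute_reward(0.3, "ART"), 0.125)
  expect_equal(compute_reward(0.6, "ART"), 0.25) # base saturates, no bonus at
  expect_equal(compute_reward(0.2, "ALT"), 0)
  expect_equal(compute_reward(-1, "ALT"), 0.50)
})

test_that("feedback loop emits one update per 100 ms and converges", {
  stream <- lateralized_stream(0.4, duration = 15)
  run <- run_feedback_loop(stream, "ART")
  expect_equal(nrow(run$trace), 141L)
  expect_equal(run$trace$t[1], 1.0)
  expect_equal(run$trace$t[141], 15.0)

  # stationary input: smoothed index and visibility settle at static values
  expect_equal(run$trace$aai[141], 0.4, tolerance = 1e-6)
  expect_equal(run$trace$faai[141], 0.4, tolerance = 1e-6)
  expect_equal(run$trace$c[141], visibility(0.4, "ART"), tolerance = 1e-6)
  expect_equal(run$reward, compute_reward(0.4, "ART"), tolerance = 1e-6)

  expect_error(
    run_feedback_loop(stream[, 1:300], "ART"),
    "shorter than one"
  )
})

test_that("feedback loop matches the per-window reference path", {
  set.seed(9)
  stream <- matrix(rnorm(6 * 7500), 6, dimnames = list(aai_channels, NULL))
  run <- run_feedback_loop(stream, "ART")
  scalar <- vapply(seq(0, 7000, 50), function(s0) {
    compute_aai(stream[, (s0 + 1):(s0 + 500), drop = FALSE])
  }, numeric(1))
  expect_equal(run$trace$aai, scalar, tolerance = 1e-12)
})

test_that("sham mode replays the supplied trace verbatim", {
  stream <- lateralized_stream(0.3, duration = 15)
  replay <- runif(141)
  run <- run_feedback_loop(stream, "ART", mode = "sham", replay = replay)
  expect_identical(run$trace$c, replay)
  expect_error(
    run_feedback_loop(stream, "ART", mode = "sham", replay = runif(10)),
    "replay trace length"
  )
  expect_error(run_feedback_loop(stream, "ART", mode = "sham"), "replay")
})
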