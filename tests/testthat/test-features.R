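test_that("trial epoching yields 111 epochs and enforces the 50% rule", {
  sig <- lateralized_stream(0.3, duration = 20)
  sig <- sig[, 1:10000]
  res <- extract_trial_aai(sig, t = trial_t()[1:10000] + 0) # default axis
  expect_equal(res$n_total, 111L)
  expect_equal(res$n_epochs, 111L)
  expect_false(res$excluded)

  # mask 60 of 111 epoch windows -> excluded by the >50% rule
  t <- trial_t()
  mask <- rep(FALSE, 10000)
  mask[t >= -12 & t < -6.05] <- TRUE # kills epochs starting in [-12, -6.05)
  res2 <- extract_trial_aai(sig, artefact_mask = mask)
  expect_true(res2$excluded)
  expect_identical(res2$reason, "artefact_rate")
  expect_true(is.na(res2$aai))

  # a small masked stretch only removes the overlapping epochs
  mask3 <- rep(FALSE, 10000)
  mask3[t >= -6 & t < -5.9] <- TRUE
  res3 <- extract_trial_aai(sig, artefact_mask = mask3)
  expect_false(res3$excluded)
  expect_lt(res3$n_epochs, 111L)
})

test_that("offline trial asymmetry equals the realtime per-step mean", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 1, seed = 12)
  ts <- simulate_trials(cfg, sides = "ART", arms = "verum", feedback = FALSE)
  sig <- ts$signal[[1]]
  t <- trial_t()
  offline <- extract_trial_aai(sig)

  stream <- sig[, t >= -15 & t < 0, drop = FALSE]
  run <- run_feedback_loop(stream, "ART")
  realtime_windows <- run$trace$aai[run$trace$t >= 4.0 - 1e-9]
  expect_equal(length(realtime_windows), 111L)
  expect_equal(offline$aai, mean(realtime_windows), tolerance = 1e-6)
})

test_that("evoked quantification recovers an injected component", {
  set.seed(51)
  t <- trial_t()
  template <- -8 * exp(-(t - 0.220)^2 / (2 * 0.03^2))
  signals <- lapply(1:6, function(i) {
    s <- blank_trial_signal()
    s["Cz", ] <- template
    s
  })
  ts <- make_trial_set(signals)
  ev <- quantify_evoked(ts, spec = erp_spec("n2"))
  expect_equal(attr(ev, "latencies")[["n2"]], 0.220, tolerance = 0.010)
  expect_equal(mean(ev$n2), -8, tolerance = 1)

  # order invariance of the group latency
  ts_perm <- ts[c(3, 1, 6, 2, 5, 4), ]
  attributes(ts_perm)[c("srate", "channels", "t_start", "fixation_onset", "stim_onset")] <-
    attributes(ts)[c("srate", "channels", "t_start", "fixation_onset", "stim_onset")]
  ev_perm <- quantify_evoked(ts_perm, spec = erp_spec("n2"))
  expect_identical(attr(ev_perm, "latencies"), attr(ev, "latencies"))
})

test_that("evoked quantification returns near-zero for null signals", {
  signals <- lapply(1:4, function(i) blank_trial_signal())
  ts <- make_trial_set(signals)
  expect_warning(ev <- quantify_evoked(ts, spec = erp_spec("p2")), "edge")
  expect_true(all(abs(ev$p2) < 1e-9))
})

test_that("re-referencing to Fz isolates the N1", {
  t <- trial_t()
  template <- -6 * exp(-(t - 0.160)^2 / (2 * 0.02^2))
  s <- blank_trial_signal()
  s["C4", ] <- template
  s["Fz", ] <- 0.5 * template # shared activity cancelled by the reference
  ev <- quantify_evoked(make_trial_set(list(s, s)), spec = erp_spec("n1"))
  expect_equal(mean(ev$n1), -3, tolerance = 0.5)
})

test_that("oscillatory features respond to injected structure", {
  set.seed(52)
  t <- trial_t()
  burst_env <- exp(-(t - 0.25)^2 / (2 * 0.05^2))
  noise_trial <- function() {
    s <- blank_trial_signal()
    s[] <- rnorm(length(s), sd = 1)
    s
  }
  with_burst <- lapply(1:4, function(i) {
    s <- noise_trial()
    s["Cz", ] <- s["Cz", ] + 4 * sin(2 * pi * 80 * t) * burst_env
    s
  })
  without <- lapply(1:4, function(i) noise_trial())
  g1 <- quantify_oscillatory(make_trial_set(with_burst))$gamma
  g0 <- quantify_oscillatory(make_trial_set(without))$gamma
  expect_gte(mean(g1) / mean(g0), 3)

  # post-stimulus alpha drop: suppressed window vs pre-stimulus reference
  drop_trials <- lapply(1:4, function(i) {
    s <- noise_trial()
    alpha <- 4 * sin(2 * pi * 10 * t)
    alpha[t >= 0] <- alpha[t >= 0] * 0.3
    s["Cz", ] <- s["Cz", ] + alpha
    s["C4", ] <- s["C4", ] + alpha
    s
  })
  ts <- make_trial_set(drop_trials)
  post <- quantify_oscillatory(ts)$alpha
  pre <- quantify_oscillatory(ts, ab_window = c(-2, -1.6))$alpha
  expect_true(all(post < pre))
})

test_that("white-noise trials yield condition-blind features", {
  set.seed(53)
  srate <- 250
  n <- 20 * srate
  signals <- lapply(1:160, function(i) {
    matrix(rnorm(length(all_channels) * n), length(all_channels), n,
      dimnames = list(all_channels, NULL))
  })
  ts <- make_trial_set(signals, srate = srate)
  osc <- quantify_oscillatory(ts)
  labels <- rep(c(0, 1), 80)
  for (f in c("alpha", "beta", "gamma")) {
    expect_lt(abs(stats::cor(osc[[f]], labels)), 0.2)
  }
})

test_that("exclusion rules match the preregistered criteria", {
  base <- tidyr::expand_grid(
    subject = 1:2, side = c("ART", "ALT"), arm = c("verum", "sham"),
    trial = 1:12
  )
  base$half <- ifelse(base$trial <= 6, 1L, 2L)
  base$rating <- 50
  base$artefact_fraction <- 0
  base$artefact_baseline <- FALSE
  base$artefact_post <- FALSE

  # invalid rating excludes the trial everywhere
  f <- base
  f$rating[1] <- 101
  out <- apply_exclusions(f)
  expect_false(out$included[1])
  expect_identical(out$reason[1], "invalid_rating")
  expect_true(all(out$included[-1]))

  # subject left with 9 surviving trials in one condition drops entirely
  f2 <- base
  drop_idx <- which(f2$subject == 2 & f2$side == "ALT" & f2$arm == "verum")[1:3]
  f2$artefact_fraction[drop_idx] <- 0.6
  out2 <- apply_exclusions(f2, min_trials = 10)
  expect_true(all(!out2$included[out2$subject == 2]))
  expect_true(all(out2$included[out2$subject == 1]))
  expect_true("too_few_trials" %in% out2$reason[out2$subject == 2])

  # artefact only after the stimulus keeps the trial for the AAI
  f3 <- base
  f3$artefact_post[5] <- TRUE
  out3 <- apply_exclusions(f3)
  expect_true(out3$included[5])
  expect_false(out3$included_erp[5])

  # wrong-hand flag removes the subject
  f4 <- base
  f4$wrong_hand <- f4$subject == 1
  out4 <- apply_exclusions(f4)
  expect_true(all(!out4$included[f4$subject == 1]))
})

test_that("exclusions are monotone under added artefacts", {
  set.seed(54)
  base <- tidyr::expand_grid(
    subject = 1:3, side = c("ART", "ALT"), arm = c("verum", "sham"),
    trial = 1:12
  )
  base$half <- 1L
  base$rating <- runif(nrow(base), 0, 100)
  base$artefact_fraction <- runif(nrow(base), 0, 0.8)
  out1 <- apply_exclusions(base)
  worse <- base
  worse$artefact_fraction <- pmin(worse$artefact_fraction + 0.2, 1)
  out2 <- apply_exclusions(worse)
  expect_true(all(out1$included | !out2$included | !out1$included))
  # no trial flips from excluded to included
  expect_true(all(!(out2$included & !out1$included)))
})

test_that("control indices implement the normalized difference", {
  expect_equal(control_index(5, 5), 0)
  expect_equal(control_index(3, 1), 0.5)
  expect_equal(control_index(80, 40), 1 / 3)
  expect_warning(out <- control_index(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("feature extraction is deterministic and complete", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 1, seed = 44)
  ts <- simulate_trials(cfg, feedback = FALSE)
  f1 <- extract_features(ts)
  f2 <- extract_features(ts)
  expect_identical(f1, f2)
  expect_equal(nrow(f1), 4L)
  expect_true(all(abs(f1$aai) <= 1))
  expect_true(all(is.finite(f1$alpha)))
})
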