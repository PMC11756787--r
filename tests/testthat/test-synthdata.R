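test_that("generation is bit-reproducible and uses subject substreams", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 2, seed = 5)
  a <- simulate_trials(cfg)
  b <- simulate_trials(cfg)
  expect_identical(a$signal, b$signal)
  expect_identical(a$rating, b$rating)
  expect_identical(a$feedback, b$feedback)

  # growing the cohort must not reshuffle earlier subjects
  small <- simulate_features(sim_config(n_subjects = 3, seed = 9))
  large <- simulate_features(sim_config(n_subjects = 6, seed = 9))
  expect_identical(small, large[large$subject <= 3, ])
})

test_that("configuration is validated", {
  expect_error(sim_config(channel_names = c("C3", "C4")), "required 10-20")
  expect_error(sim_config(sampling_rate = 100), "sampling_rate")
  expect_error(sim_config(n_subjects = 0))
})

test_that("null generator shows no ART-ALT asymmetry difference", {
  ps <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_subjects = 30, attention_effect = 0, neurofeedback_gain = 0,
      time_slope = 0, seed = s
    )
    ft <- simulate_features(cfg)
    m <- tapply(ft$aai_true, list(ft$subject, ft$side), mean)
    stats::t.test(m[, "ART"], m[, "ALT"], paired = TRUE)$p.value
  }, numeric(1))
  expect_gte(sum(ps > 0.01), 19)
  # pooled across seeds the null holds comfortably
  expect_gt(mean(ps), 0.1)
})

test_that("attention effect calibrated to d = 0.8 is recovered", {
  # analytic scaling: d * sqrt(sd_attn^2 + trial_sd^2 / n_trials) = 0.042
  ds <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_subjects = 40, attention_effect = 0.042,
      neurofeedback_gain = 0, time_slope = 0, seed = s
    )
    ft <- simulate_features(cfg)
    m <- tapply(ft$aai_true, list(ft$subject, ft$side), mean)
    d <- m[, "ART"] - m[, "ALT"]
    mean(d) / stats::sd(d)
  }, numeric(1))
  expect_gte(stats::median(ds), 0.5)
  expect_lte(stats::median(ds), 1.1)
})

test_that("asymmetry targets stay inside the index range", {
  cfg <- sim_config(
    n_subjects = 5, attention_effect = 1.5, aai_subject_sd = 0.5, seed = 3
  )
  ft <- simulate_features(cfg)
  expect_true(all(ft$aai_true >= -1 & ft$aai_true <= 1))
  expect_true(all(ft$rating >= 0 & ft$rating <= 100))
})

test_that("positive mediation strength yields positive AAI-rating coupling", {
  slopes <- vapply(1:20, function(s) {
    cfg <- sim_config(
      n_subjects = 1, n_trials_per_condition = 40, beta_m = 20, seed = s
    )
    ft <- simulate_features(cfg)
    stats::coef(stats::lm(rating ~ x + aai_true, data = ft))[["aai_true"]]
  }, numeric(1))
  expect_gte(mean(slopes > 0), 0.9)
})

test_that("rendered regulation signal carries a detectable alpha peak", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_condition = 1, seed = 31)
  ts <- simulate_trials(cfg, sides = "ART", arms = "verum", feedback = FALSE)
  sig <- ts$signal[[1]]
  t <- trial_t()
  reg <- sig[, t >= -12 & t < 0, drop = FALSE]
  spec <- function(ch, band) {
    mean(vapply(seq(1, ncol(reg) - 499, by = 500), function(s0) {
      aaipipe:::window_band_power(reg[ch, s0:(s0 + 499), drop = FALSE],
        500, band)
    }, numeric(1)))
  }
  for (ch in c("C4", "CP4", "C3")) {
    alpha <- spec(ch, c(8, 12))
    flank <- (spec(ch, c(4, 6)) + spec(ch, c(15, 17))) / 2
    expect_gt(alpha, 3 * flank)
  }
})

test_that("stationary lateralization is recovered analytically", {
  # noise-free constructed streams: extracted trial AAI equals the
  # analytic asymmetry of the band powers
  for (a in c(-0.5, 0.2, 0.7)) {
    sig <- lateralized_stream(a, duration = 20)[, 1:10000]
    expect_equal(extract_trial_aai(sig)$aai, a, tolerance = 1e-6)
  }
  # with additive broadband noise the median error stays within 0.05
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    sig <- 4 * lateralized_stream(0.3, duration = 20)[, 1:10000]
    sig <- sig + matrix(rnorm(length(sig), sd = 0.5), nrow(sig))
    abs(extract_trial_aai(sig)$aai - 0.3)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("rendered lateralization survives the offline analysis path", {
  cfg <- sim_config(
    n_subjects = 6, n_trials_per_condition = 1, attention_effect = 0,
    aai_subject_sd = 0.3, aai_trial_sd = 0.02, seed = 17
  )
  ts <- simulate_trials(cfg, sides = "ART", arms = "verum", feedback = FALSE)
  got <- vapply(ts$signal, function(s) extract_trial_aai(s)$aai, numeric(1))
  # pink noise adds symmetric band power, attenuating towards zero
  expect_gt(stats::cor(got, ts$aai_true), 0.9)
  expect_true(all(abs(got) <= abs(ts$aai_true) + 0.05))
})

test_that("yoked sham replays the donor trace but stays independent", {
  cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 3, seed = 3)
  donor <- simulate_trials(cfg, subjects = 1, sides = "ART", arms = "verum")
  recipient <- simulate_trials(cfg,
    subjects = 2, sides = "ART", arms = "verum", feedback = FALSE
  )
  sham <- simulate_yoked_sham(donor, recipient)
  expect_identical(sham$feedback, donor$feedback)
  expect_identical(sham$reward, donor$reward)
  expect_equal(nrow(sham), nrow(donor))
  expect_true(all(sham$arm == "sham"))
  # recipient EEG untouched
  expect_identical(sham$signal, recipient$signal)

  expect_error(simulate_yoked_sham(donor, recipient[1:2, ]), "mismatch")
  expect_error(simulate_yoked_sham(recipient, recipient), "no feedback")
})

test_that("sham asymmetry is uncorrelated with the displayed visibility", {
  rs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 40, seed = s)
    donor <- simulate_trials(cfg, subjects = 1, sides = "ART", arms = "verum")
    shown <- vapply(donor$feedback, function(tr) mean(tr$c), numeric(1))
    recipient <- simulate_features(cfg)
    rec_aai <- recipient$aai_true[
      recipient$subject == 2 & recipient$side == "ART" &
        recipient$arm == "sham"
    ]
    stats::cor(rec_aai, shown)
  }, numeric(1))
  expect_lt(stats::median(abs(rs)), 0.2)
})
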