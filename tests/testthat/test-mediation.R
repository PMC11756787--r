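test_that("mediation input recodes and centers as specified", {
  cfg <- sim_config(n_subjects = 3, n_trials_per_condition = 6, seed = 71)
  ft <- simulate_features(cfg)
  ft$aai <- ft$aai_true
  inp <- mediation_input(ft, "verum")
  expect_setequal(unique(inp$x), c(-1, 1))
  cen <- tapply(inp$m, inp$subject, mean)
  expect_true(all(abs(cen) < 1e-9))
  expect_equal(nrow(inp), 3 * 2 * 6)
})

test_that("known path coefficients are recovered", {
  md <- simulate_mediation_data(
    20, 60, a = 0.5, b = 20, cprime = 0, sigma_ab = 0, seed = 72
  )
  fit <- fit_multilevel_mediation(md, iter = 1500, warmup = 400, seed = 1)
  expect_true(fit$diagnostics$converged)
  p <- fit$paths
  ab <- p[p$path == "ab", ]
  expect_lt(ab$ci_lower, 10)
  expect_gt(ab$ci_upper, 10)
  expect_true(ab$present)
  expect_equal(p$estimate[p$path == "a"], 0.5, tolerance = 0.15)
  expect_equal(p$estimate[p$path == "b"], 20, tolerance = 4)
})

test_that("a null mediated path yields an interval covering zero", {
  md <- simulate_mediation_data(
    20, 60, a = 0.5, b = 0, cprime = 0, seed = 73
  )
  fit <- fit_multilevel_mediation(md, iter = 1500, warmup = 400, seed = 2)
  ab <- fit$paths[fit$paths$path == "ab", ]
  expect_lte(ab$ci_lower, 0)
  expect_gte(ab$ci_upper, 0)
  expect_false(fit$mediation_found)
})

test_that("posterior identities hold draw by draw", {
  md <- simulate_mediation_data(15, 40, a = 0.4, b = 10, seed = 74)
  fit <- fit_multilevel_mediation(md, iter = 1000, warmup = 300, seed = 3)
  d <- fit$draws
  expect_equal(d[, "ab"], d[, "a"] * d[, "b"] + d[, "sigma_ab"],
    tolerance = 1e-12)
  expect_equal(d[, "c"], d[, "cprime"] + d[, "ab"], tolerance = 1e-12)
})

test_that("estimates ignore a constant shift of one subject's outcome", {
  md <- simulate_mediation_data(15, 40, a = 0.4, b = 10, seed = 75)
  shifted <- md
  shifted$y[shifted$subject == 1] <- shifted$y[shifted$subject == 1] + 500
  f1 <- fit_multilevel_mediation(md, iter = 1500, warmup = 400, seed = 4)
  f2 <- fit_multilevel_mediation(shifted, iter = 1500, warmup = 400, seed = 4)
  for (p in c("a", "b", "ab")) {
    expect_equal(
      f1$paths$estimate[f1$paths$path == p],
      f2$paths$estimate[f2$paths$path == p],
      tolerance = 0.2 * max(1, abs(f1$paths$estimate[f1$paths$path == p]))
    )
  }
})

test_that("replicated single-subject data approach the OLS solution", {
  set.seed(76)
  n <- 200
  x <- rep(c(-1, 1), n / 2)
  m <- 0.5 * x + rnorm(n, 0, 0.2)
  y <- 50 + 1 * x + 15 * m + rnorm(n, 0, 5)
  md <- purrr::map_dfr(1:10, ~ tibble::tibble(subject = .x, x = x, m = m, y = y))
  fit <- fit_multilevel_mediation(md, iter = 1500, warmup = 400,
    center_m = FALSE, seed = 5)
  ols_m <- stats::coef(stats::lm(m ~ x))
  ols_y <- stats::coef(stats::lm(y ~ x + m))
  p <- fit$paths
  expect_equal(p$estimate[p$path == "a"], ols_m[["x"]], tolerance = 0.05)
  expect_equal(p$estimate[p$path == "b"], ols_y[["m"]], tolerance = 0.5)
  expect_equal(p$estimate[p$path == "cprime"], ols_y[["x"]], tolerance = 0.5)
})

test_that("posterior intervals shrink with more trials per subject", {
  f_small <- fit_multilevel_mediation(
    simulate_mediation_data(15, 20, a = 0.5, b = 10, seed = 77),
    iter = 1200, warmup = 300, seed = 6
  )
  f_large <- fit_multilevel_mediation(
    simulate_mediation_data(15, 160, a = 0.5, b = 10, seed = 77),
    iter = 1200, warmup = 300, seed = 6
  )
  width <- function(f, p) {
    r <- f$paths[f$paths$path == p, ]
    r$ci_upper - r$ci_lower
  }
  expect_lt(width(f_large, "b"), width(f_small, "b"))
  expect_lt(width(f_large, "a"), width(f_small, "a"))
})

test_that("comparing a fit to itself favours the null on every path", {
  md <- simulate_mediation_data(15, 40, a = 0.5, b = 15, seed = 78)
  fit <- fit_multilevel_mediation(md, iter = 1200, warmup = 300, seed = 7)
  cmp <- compare_mediation(fit, fit)
  expect_identical(cmp$status, "done")
  expect_true(all(cmp$tests$bf10 < 1))
})

test_that("moderation recovery separates verum from sham cohorts", {
  verum <- fit_multilevel_mediation(
    simulate_mediation_data(40, 80, a = 0.5, b = 20, sigma_ab = 0, seed = 79),
    iter = 1200, warmup = 300, seed = 8
  )
  sham <- fit_multilevel_mediation(
    simulate_mediation_data(40, 80, a = 0.5, b = 0, sigma_ab = 0, seed = 80),
    iter = 1200, warmup = 300, seed = 9
  )
  cmp <- compare_mediation(verum, sham)
  expect_identical(cmp$status, "done")
  expect_gte(cmp$tests$bf10[cmp$tests$path == "ab"], 3)
})

test_that("the moderation comparison is skipped without a mediation effect", {
  null_fit <- fit_multilevel_mediation(
    simulate_mediation_data(12, 30, a = 0.4, b = 0, seed = 81),
    iter = 1000, warmup = 300, seed = 10
  )
  cmp <- compare_mediation(null_fit, null_fit)
  expect_identical(cmp$status, "skipped")
  expect_null(cmp$tests)
  expect_match(cmp$reason, "no mediation")

  other <- fit_multilevel_mediation(
    simulate_mediation_data(10, 30, a = 0.4, b = 0, seed = 82),
    iter = 1000, warmup = 300, seed = 11
  )
  expect_error(compare_mediation(null_fit, other), "subject set")
})
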