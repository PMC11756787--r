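#' Draw the per-trial statistical model of a synthetic experiment
#'
#' Fast layer of the generator: draws, for every subject x condition x
#' trial, the ground-truth asymmetry target `aai_true` and the pain rating
#' without rendering any EEG. [simulate_trials()] renders signals for
#' exactly these draws, so statistical-structure checks and large cohorts
#' can run at this level while signal-path checks use the EEG level.
#'
#' Per trial the asymmetry target is
#' `u_j + s * (attn_j / 2) + s * v * (gain / 2) + s * slope * (trial - 1) + e`,
#' with `s = +1` (ART) / `-1` (ALT), `v = 1` for verum, subject baseline
#' `u_j` and subject attention effect `attn_j` drawn from normals, and
#' trial noise `e`; targets are clipped to `[-0.95, 0.95]`. The rating is
#' `rating_mean + r_j + beta_x * X + beta_m * aai_true + noise` clipped to
#' `[0, 100]`, with `X = -1` (ART) / `+1` (ALT).
#'
#' @param config a [sim_config()].
#' @return tibble with one row per trial: `subject`, `side` (ART/ALT),
#'   `arm` (verum/sham), `session`, `trial`, `half`, `aai_true`, `x`,
#'   `rating`.
#' @export
simulate_features <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nt <- config$n_trials_per_condition
  cells <- tidyr::expand_grid(
    side = c("ART", "ALT"),
    arm = c("verum", "sham"),
    trial = seq_len(nt)
  )
  purrr::map_dfr(seq_len(config$n_subjects), function(j) {
    set.seed(subject_seed(config, j))
    u <- stats::rnorm(1, 0, config$aai_subject_sd)
    attn <- stats::rnorm(1, config$attention_effect, config$attention_effect_sd)
    r_j <- stats::rnorm(1, 0, config$rating_subject_sd)
    df <- cells
    s <- ifelse(df$side == "ART", 1, -1)
    v <- as.numeric(df$arm == "verum")
    mu <- u + s * attn / 2 + s * v * config$neurofeedback_gain / 2 +
      s * config$time_slope * (df$trial - 1)
    aai <- pmin(pmax(mu + stats::rnorm(nrow(df), 0, config$aai_trial_sd), -0.95), 0.95)
    x <- ifelse(df$side == "ART", -1, 1)
    rating <- config$rating_mean + r_j + config$beta_x * x +
      config$beta_m * aai + stats::rnorm(nrow(df), 0, config$rating_noise_sd)
    tibble::tibble(
      subject = j,
      side = df$side,
      arm = df$arm,
      session = ifelse(df$arm == "verum", 1L, 2L),
      trial = df$trial,
      half = ifelse(df$trial <= ceiling(nt / 2), 1L, 2L),
      aai_true = aai,
      x = x,
      rating = pmin(pmax(rating, 0), 100)
    )
  })
}

#' Generate per-subject condition averages directly
#'
#' Draws the 8 per-subject cell means (ART/ALT x verum/sham x first/second
#' half) that the adaptive hypothesis pipeline consumes, with the three
#' experimental effects parameterized as paired-contrast Cohen's d values.
#' Useful for pattern-recovery simulations where rendering trials is
#' unnecessary.
#'
#' Cell model: `u_j + s * att / 2 + s * v * nf / 2 + s * h * time / 2 + e`
#' with `s` the side sign, `v` the verum indicator, `h` the second-half
#' indicator, and `e ~ N(0, cell_sd)`. Effects are scaled internally so
#' that each targeted paired contrast has the requested d.
#'
#' @param n_subjects number of subjects.
#' @param d_time,d_nf,d_att Cohen's d of the time, neurofeedback and
#'   attention contrasts (0 for null effects).
#' @param cell_sd within-cell noise SD (index units, default 0.05).
#' @param subject_sd between-subject baseline SD (default 0.08).
#' @param seed integer seed.
#' @return tibble with columns `subject`, `side`, `arm`, `half`, `value`
#'   (one row per subject and cell), suitable for [run_aai_pipeline()].
#' @export
simulate_condition_averages <- function(n_subjects,
                                        d_time = 0, d_nf = 0, d_att = 0,
                                        cell_sd = 0.05, subject_sd = 0.08,
                                        seed = 1L) {
  set.seed(seed)
  sd_pair <- sqrt(2) * cell_sd
  time_eff <- d_time * 2 * sd_pair
  nf_eff <- d_nf * 2 * sd_pair
  att_eff <- d_att * sd_pair # tested as a single ART-vs-ALT contrast
  cells <- tidyr::expand_grid(
    subject = seq_len(n_subjects),
    side = c("ART", "ALT"),
    arm = c("verum", "sham"),
    half = 1:2
  )
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  s <- ifelse(cells$side == "ART", 1, -1)
  v <- as.numeric(cells$arm == "verum")
  h <- cells$half - 1L
  cells$value <- u[cells$subject] + s * att_eff / 2 + s * v * nf_eff / 2 +
    s * h * time_eff / 2 + stats::rnorm(nrow(cells), 0, cell_sd)
  cells
}

#' Generate single-trial data for the multilevel mediation model
#'
#' Draws trials from the 1-1-1 mediation model the package fits: subject
#' coefficient vectors around group means, a mediator regression
#' `M = dm_j + a_j X + e`, and an outcome regression
#' `Y = mean + dy_j + c'_j X + b_j M + e`. The `a` and `b` subject
#' coefficients can covary (`sigma_ab`), so the true indirect effect is
#' `a * b + sigma_ab`.
#'
#' @param n_subjects,n_trials subjects and trials per subject (trials are
#'   split evenly between `X = -1` and `X = +1`).
#' @param a,b,cprime group-level path coefficients.
#' @param sigma_ab covariance of the subject-level `a` and `b`.
#' @param sd_a,sd_b,sd_cprime between-subject coefficient SDs.
#' @param sd_intercept_m,sd_intercept_y between-subject intercept SDs.
#' @param sigma_m,sigma_y residual SDs of mediator and outcome.
#' @param y_mean grand mean of the outcome (default 50).
#' @param seed integer seed.
#' @return tibble with `subject`, `x`, `m`, `y` (one row per trial).
#' @export
simulate_mediation_data <- function(n_subjects, n_trials,
                                    a = 0.5, b = 0, cprime = 0,
                                    sigma_ab = 0,
                                    sd_a = 0.1, sd_b = 2, sd_cprime = 2,
                                    sd_intercept_m = 0.05, sd_intercept_y = 10,
                                    sigma_m = 0.2, sigma_y = 10,
                                    y_mean = 50, seed = 1L) {
  stopifnot(n_subjects >= 1, n_trials >= 2)
  set.seed(seed)
  if (abs(sigma_ab) > sd_a * sd_b) {
    stop("sigma_ab exceeds the bound implied by sd_a and sd_b")
  }
  cov_ab <- matrix(c(sd_a^2, sigma_ab, sigma_ab, sd_b^2), 2, 2)
  ab_j <- matrix(stats::rnorm(2 * n_subjects), n_subjects, 2) %*% chol(cov_ab)
  x <- rep(c(-1, 1), length.out = n_trials)
  purrr::map_dfr(seq_len(n_subjects), function(j) {
    aj <- a + ab_j[j, 1]
    bj <- b + ab_j[j, 2]
    cpj <- cprime + stats::rnorm(1, 0, sd_cprime)
    dmj <- stats::rnorm(1, 0, sd_intercept_m)
    dyj <- stats::rnorm(1, 0, sd_intercept_y)
    m <- dmj + aj * x + stats::rnorm(n_trials, 0, sigma_m)
    y <- y_mean + dyj + cpj * x + bj * m + stats::rnorm(n_trials, 0, sigma_y)
    tibble::tibble(subject = j, x = x, m = m, y = y)
  })
}
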