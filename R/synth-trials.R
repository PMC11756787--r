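#' Render a synthetic EEG trial set
#'
#' Renders multichannel EEG for the per-trial draws of
#' [simulate_features()]: pink-noise background on every channel, a 10 Hz
#' alpha source whose amplitude over the right ({C4, CP4, CP6}) and left
#' ({C3, CP3, CP5}) somatosensory groups is lateralized so that the band
#' power ratio reproduces the trial's asymmetry target, laser-evoked
#' N1/N2/P2 deflections, a post-stimulus gamma burst at Cz, and
#' post-stimulus alpha/beta suppression. Trials span `[-18, 2)` s around
#' the stimulus at `t = 0` (fixation onset at -18 s, regulation period
#' `[-15, 0)`). For verum trials the real-time feedback loop is run on the
#' regulation period and its trace stored.
#'
#' @param config a [sim_config()].
#' @param subjects integer vector of subject indices to render (default
#'   all); per-subject substreams keep other subjects' draws unchanged.
#' @param sides,arms subsets of `c("ART", "ALT")` / `c("verum", "sham")`
#'   to render (defaults: all), for cheap single-condition fixtures.
#' @param feedback logical: run [run_feedback_loop()] on verum trials and
#'   store the trace (default TRUE).
#' @return a `trial_set`: tibble with one row per trial (`subject`,
#'   `side`, `arm`, `session`, `trial`, `half`, `aai_true`, `x`, `rating`,
#'   `signal` list-column of channels x samples matrices, `feedback`
#'   list-column, `reward`), with attributes `srate`, `channels`,
#'   `t_start`, `fixation_onset`, `stim_onset`.
#' @export
simulate_trials <- function(config, subjects = NULL,
                            sides = c("ART", "ALT"),
                            arms = c("verum", "sham"),
                            feedback = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  feats <- simulate_features(config)
  if (is.null(subjects)) subjects <- seq_len(config$n_subjects)
  feats <- dplyr::filter(
    feats,
    .data$subject %in% subjects, .data$side %in% sides, .data$arm %in% arms
  )

  srate <- config$sampling_rate
  tt <- trial_time_axis(srate)
  reg <- which(tt >= -15 & tt < 0)

  rows <- purrr::map(seq_len(nrow(feats)), function(i) {
    row <- feats[i, ]
    # rendering substream: independent of the feature draws, reproducible
    set.seed(subject_seed(config, row$subject) +
      1000L * match(row$arm, c("verum", "sham")) +
      100000L * match(row$side, c("ART", "ALT")) + row$trial)
    sig <- render_trial_signal(config, row$aai_true, tt)
    fb <- NULL
    rew <- NA_real_
    if (feedback && row$arm == "verum") {
      run <- run_feedback_loop(sig[, reg, drop = FALSE],
        condition = row$side, srate = srate
      )
      fb <- run$trace
      rew <- run$reward
    }
    list(signal = sig, feedback = fb, reward = rew)
  })
  feats$signal <- purrr::map(rows, "signal")
  feats$feedback <- purrr::map(rows, "feedback")
  feats$reward <- purrr::map_dbl(rows, "reward")
  new_trial_set(feats, config)
}

trial_time_axis <- function(srate, t_start = -18, t_end = 2) {
  seq(t_start, t_end - 1 / srate, by = 1 / srate)
}

new_trial_set <- function(df, config) {
  out <- tibble::new_tibble(df, class = "trial_set")
  attr(out, "srate") <- config$sampling_rate
  attr(out, "channels") <- config$channel_names
  attr(out, "t_start") <- -18
  attr(out, "fixation_onset") <- -18
  attr(out, "stim_onset") <- 0
  out
}

# one trial's channels x samples matrix
render_trial_signal <- function(config, aai, tt) {
  ch <- config$channel_names
  srate <- config$sampling_rate
  n <- length(tt)
  sig <- matrix(0, length(ch), n, dimnames = list(ch, NULL))

  for (k in seq_along(ch)) sig[k, ] <- pink_noise(n, srate) * config$noise_sd

  # common alpha source, amplitude-lateralized per hemisphere group;
  # power ratio (1 + a) / (1 - a) makes the asymmetry index equal a
  phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.3 * sin(2 * pi * 0.4 * (tt + 18) + stats::runif(1, 0, 2 * pi))
  src <- sin(2 * pi * 10 * tt + phase) * env
  active <- tt >= -15
  supp <- 1 - config$alpha_suppression *
    pmin(pmax((tt - 0.2) / 0.2, 0), 1) # post-stimulus desynchronization
  a_r <- config$alpha_amplitude * sqrt(1 + aai)
  a_l <- config$alpha_amplitude * sqrt(1 - aai)
  alpha_wave <- src * active * supp
  for (nm in c("C4", "CP4", "CP6")) sig[nm, ] <- sig[nm, ] + a_r * alpha_wave
  for (nm in c("C3", "CP3", "CP5")) sig[nm, ] <- sig[nm, ] + a_l * alpha_wave

  # midline alpha and beta, also suppressed after the stimulus
  mid <- intersect(c("Cz", "CPz", "C2", "CP2"), ch)
  mid_alpha <- sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) * active * supp
  beta_wave <- sin(2 * pi * 20 * tt + stats::runif(1, 0, 2 * pi)) * active * supp
  for (nm in mid) {
    sig[nm, ] <- sig[nm, ] + 0.5 * config$alpha_amplitude * mid_alpha +
      0.3 * config$alpha_amplitude * beta_wave
  }

  # laser-evoked potentials (Gaussian-windowed deflections)
  g <- function(lat_ms, width_s) exp(-(tt - lat_ms / 1000)^2 / (2 * width_s^2))
  amp <- config$erp_amplitudes
  lat <- config$erp_latencies
  n1 <- amp[["n1"]] * g(lat[["n1"]], 0.020)
  sig["C4", ] <- sig["C4", ] + n1
  sig["CP4", ] <- sig["CP4", ] + 0.5 * n1
  n2 <- amp[["n2"]] * g(lat[["n2"]], 0.030)
  p2 <- amp[["p2"]] * g(lat[["p2"]], 0.050)
  sig["Cz", ] <- sig["Cz", ] + n2 + p2
  sig["CPz", ] <- sig["CPz", ] + 0.6 * (n2 + p2)
  for (nm in intersect(c("C2", "CP2"), ch)) {
    sig[nm, ] <- sig[nm, ] + 0.4 * (n2 + p2)
  }

  # post-stimulus gamma burst at the vertex
  g_amp <- sqrt(config$gamma_burst_power) * 1.0
  burst <- g_amp * sin(2 * pi * 80 * tt + stats::runif(1, 0, 2 * pi)) *
    exp(-(tt - 0.25)^2 / (2 * 0.05^2))
  sig["Cz", ] <- sig["Cz", ] + burst

  # optional amplitude artefact (exercises the artefact stub)
  if (config$artefact_prob > 0 && stats::runif(1) < config$artefact_prob) {
    onset <- stats::runif(1, -14, 1.5)
    idx <- which(tt >= onset & tt < onset + 0.2)
    chan <- sample(length(ch), 1)
    sig[chan, idx] <- sig[chan, idx] +
      sample(c(-1, 1), 1) * config$artefact_amplitude
  }
  sig
}

# 1/f-amplitude background noise, unit variance
pink_noise <- function(n, srate) {
  x <- stats::rnorm(n)
  xf <- stats::fft(x)
  f <- (seq_len(n) - 1) * srate / n
  f <- pmin(f, srate - f) # two-sided frequency magnitude
  scale <- 1 / sqrt(pmax(f, 1)) # flat below 1 Hz
  scale[1] <- 0
  out <- Re(stats::fft(xf * scale, inverse = TRUE)) / n
  out / stats::sd(out)
}

#' Yoke sham trials to a donor's verum feedback
#'
#' Implements yoked (replay) sham feedback: the recipient's trials keep
#' their own EEG, ratings and asymmetry draws, but their displayed
#' feedback trace and reward are taken trial-for-trial from the donor's
#' verum run, so the displayed signal is independent of the recipient's
#' brain activity.
#'
#' @param donor a `trial_set` of verum trials carrying feedback traces.
#' @param recipient a `trial_set` of the same number of trials (matched
#'   sides) whose feedback will be replaced.
#' @return the recipient `trial_set` with `feedback` and `reward` replaced
#'   by the donor's, and `arm` set to `"sham"`.
#' @export
simulate_yoked_sham <- function(donor, recipient) {
  stopifnot(inherits(donor, "trial_set"), inherits(recipient, "trial_set"))
  if (nrow(donor) != nrow(recipient)) {
    stop(
      "trial-count mismatch: donor has ", nrow(donor),
      " trials, recipient ", nrow(recipient)
    )
  }
  if (any(purrr::map_lgl(donor$feedback, is.null))) {
    stop("donor trials carry no feedback traces")
  }
  if (!all(donor$side == recipient$side)) {
    stop("donor and recipient conditions (sides) must match trial-for-trial")
  }
  recipient$feedback <- donor$feedback
  recipient$reward <- donor$reward
  recipient$arm <- "sham"
  recipient
}
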