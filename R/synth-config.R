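#' Configuration for a synthetic neurofeedback experiment
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults emulate the within-subject, bidirectional design the
#' package analyzes: 4 conditions (ART/ALT x verum/sham), 40 trials per
#' condition, 15 s regulation periods sampled at 500 Hz, laser stimulus at
#' `t = 0`, pain ratings on a 0--100 numerical rating scale, and a null
#' pain model (`beta_x = beta_m = 0`) in which neither condition nor
#' trial-wise asymmetry moves the ratings.
#'
#' @param n_subjects number of participants.
#' @param n_trials_per_condition trials per condition (default 40).
#' @param sampling_rate Hz (default 500); must exceed twice the highest
#'   synthesized frequency (gamma, 90 Hz).
#' @param channel_names montage labels; must include C3, C4, CP3, CP4,
#'   CP5, CP6, Cz, CPz, C2, CP2, Fz.
#' @param attention_effect AAI shift between ART and ALT (index units).
#' @param neurofeedback_gain additional AAI shift for verum vs sham.
#' @param time_slope AAI drift per trial (index units/trial).
#' @param attention_effect_sd between-subject SD of the attention effect.
#' @param aai_subject_sd SD of the subject baseline asymmetry.
#' @param aai_trial_sd trial-to-trial SD of the asymmetry target.
#' @param erp_amplitudes named numeric, microvolts, components n1/n2/p2
#'   (n1 and n2 negative).
#' @param erp_latencies named numeric, milliseconds post stimulus.
#' @param gamma_burst_power relative post-stimulus gamma power increase.
#' @param alpha_suppression relative post-stimulus alpha/beta amplitude
#'   drop, in `[0, 1)`.
#' @param alpha_amplitude base 10 Hz amplitude in microvolts.
#' @param noise_sd pink-background-noise SD in microvolts.
#' @param rating_mean grand mean pain rating (NRS units).
#' @param rating_subject_sd between-subject SD of the rating intercept.
#' @param rating_noise_sd trial-level rating noise SD.
#' @param beta_x effect of condition (ART = -1, ALT = +1) on the rating.
#' @param beta_m effect of the trial asymmetry on the rating (NRS units
#'   per AAI unit); the mediated path.
#' @param artefact_prob per-trial probability of an injected amplitude
#'   artefact (for exercising the artefact stub; default 0).
#' @param artefact_amplitude artefact magnitude in microvolts.
#' @param seed global integer seed; expanded into per-subject substreams
#'   so that growing `n_subjects` leaves earlier subjects unchanged.
#' @return validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_subjects = 2, n_trials_per_condition = 4)
#' @export
sim_config <- function(n_subjects = 10L,
                       n_trials_per_condition = 40L,
                       sampling_rate = 500,
                       channel_names = c(
                         "C3", "C4", "CP3", "CP4", "CP5", "CP6",
                         "Cz", "CPz", "C2", "CP2", "Fz"
                       ),
                       attention_effect = 0.10,
                       neurofeedback_gain = 0.05,
                       time_slope = 0.001,
                       attention_effect_sd = 0.05,
                       aai_subject_sd = 0.08,
                       aai_trial_sd = 0.10,
                       erp_amplitudes = c(n1 = -6, n2 = -10, p2 = 12),
                       erp_latencies = c(n1 = 160, n2 = 230, p2 = 350),
                       gamma_burst_power = 1,
                       alpha_suppression = 0.4,
                       alpha_amplitude = 4,
                       noise_sd = 5,
                       rating_mean = 50,
                       rating_subject_sd = 15,
                       rating_noise_sd = 10,
                       beta_x = 0,
                       beta_m = 0,
                       artefact_prob = 0,
                       artefact_amplitude = 150,
                       seed = 1L) {
  required <- c(
    "C3", "C4", "CP3", "CP4", "CP5", "CP6", "Cz", "CPz", "C2", "CP2", "Fz"
  )
  missing <- setdiff(required, channel_names)
  if (length(missing)) {
    stop(
      "channel_names must include the required 10-20 labels; missing: ",
      paste(missing, collapse = ", ")
    )
  }
  stopifnot(
    n_subjects >= 1, n_trials_per_condition >= 1,
    sampling_rate > 2 * 90,
    all(c("n1", "n2", "p2") %in% names(erp_amplitudes)),
    all(c("n1", "n2", "p2") %in% names(erp_latencies)),
    alpha_suppression >= 0, alpha_suppression < 1,
    artefact_prob >= 0, artefact_prob <= 1
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_trials_per_condition = as.integer(n_trials_per_condition),
      sampling_rate = sampling_rate,
      channel_names = channel_names,
      attention_effect = attention_effect,
      neurofeedback_gain = neurofeedback_gain,
      time_slope = time_slope,
      attention_effect_sd = attention_effect_sd,
      aai_subject_sd = aai_subject_sd,
      aai_trial_sd = aai_trial_sd,
      erp_amplitudes = erp_amplitudes,
      erp_latencies = erp_latencies,
      gamma_burst_power = gamma_burst_power,
      alpha_suppression = alpha_suppression,
      alpha_amplitude = alpha_amplitude,
      noise_sd = noise_sd,
      rating_mean = rating_mean,
      rating_subject_sd = rating_subject_sd,
      rating_noise_sd = rating_noise_sd,
      beta_x = beta_x,
      beta_m = beta_m,
      artefact_prob = artefact_prob,
      artefact_amplitude = artefact_amplitude,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# deterministic per-subject substream seed (kept below 2^31)
subject_seed <- function(config, subject) {
  as.integer((as.double(config$seed) + 7919 * subject) %% .Machine$integer.max)
}
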