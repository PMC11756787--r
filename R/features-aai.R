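#' Amplitude-threshold artefact detection
#'
#' Minimal artefact stub: flags every sample at which any channel exceeds
#' a fixed absolute amplitude. It stands in for a full automatic
#' preprocessing pipeline and is only meant to drive the epoch-rejection
#' and trial-exclusion logic.
#'
#' @param signal channels x samples numeric matrix.
#' @param threshold absolute amplitude threshold in microvolts
#'   (default 100).
#' @return logical vector, one entry per sample.
#' @export
detect_artefacts <- function(signal, threshold = 100) {
  stopifnot(is.matrix(signal))
  apply(abs(signal) > threshold, 2, any)
}

#' Offline single-trial asymmetry index
#'
#' Re-derives the trial's asymmetry following the same procedure as the
#' real-time engine: the last 12 s of the regulation period (`[-12, 0)` s
#' relative to the stimulus) are segmented into 1,000 ms epochs with
#' 900 ms overlap (111 epochs), epochs containing artefact samples are
#' rejected, each surviving epoch is scored with [compute_aai()], and the
#' trial value is the mean across surviving epochs. A trial with more
#' than 50% of its epochs rejected is excluded.
#'
#' @param signal channels x samples matrix for one trial.
#' @param t time axis in seconds (stimulus at 0); defaults to the
#'   `[-18, 2)` axis of [simulate_trials()].
#' @param artefact_mask logical per-sample mask (TRUE = artefact), or
#'   NULL.
#' @param srate sampling rate in Hz.
#' @param span length of the analyzed pre-stimulus interval in seconds
#'   (default 12).
#' @return list: `aai` (NA when excluded), `n_epochs` surviving,
#'   `n_total`, `artefact_fraction`, `excluded`, `reason`.
#' @export
extract_trial_aai <- function(signal, t = NULL, artefact_mask = NULL,
                              srate = 500, span = 12) {
  stopifnot(is.matrix(signal))
  if (is.null(t)) t <- trial_time_axis(srate)
  if (length(t) != ncol(signal)) stop("time axis does not match signal")
  keep <- which(t >= -span & t < 0)
  if (length(keep) < srate) stop("regulation data must cover the last ", span, " s")
  win <- as.integer(round(srate))
  step <- as.integer(round(0.1 * srate))
  starts <- seq.int(keep[1], keep[length(keep)] - win + 1L, by = step)
  n_total <- length(starts)
  if (is.null(artefact_mask)) artefact_mask <- rep(FALSE, ncol(signal))
  bad <- vapply(starts, function(s0) {
    any(artefact_mask[s0:(s0 + win - 1L)])
  }, logical(1))
  frac <- mean(bad)
  if (sum(bad) > n_total / 2) {
    return(list(
      aai = NA_real_, n_epochs = sum(!bad), n_total = n_total,
      artefact_fraction = frac, excluded = TRUE, reason = "artefact_rate"
    ))
  }
  vals <- vapply(starts[!bad], function(s0) {
    compute_aai(signal[, s0:(s0 + win - 1L), drop = FALSE], srate = srate)
  }, numeric(1))
  list(
    aai = mean(vals), n_epochs = sum(!bad), n_total = n_total,
    artefact_fraction = frac, excluded = FALSE, reason = NA_character_
  )
}

#' Single-trial feature table of a trial set
#'
#' Runs the full offline quantification over a `trial_set`: trial
#' asymmetry ([extract_trial_aai()]), evoked N1/N2/P2 amplitudes
#' ([quantify_evoked()]), induced alpha/beta/gamma power
#' ([quantify_oscillatory()]), artefact bookkeeping, and the pain rating,
#' one row per trial.
#'
#' @param trials a `trial_set` from [simulate_trials()].
#' @param artefact_threshold amplitude threshold passed to
#'   [detect_artefacts()].
#' @return tibble (FeatureTable) with identifiers (`subject`, `side`,
#'   `arm`, `trial`, `half`), features (`aai`, `n1`, `n2`, `p2`, `alpha`,
#'   `beta`, `gamma`, `rating`), and bookkeeping (`artefact_fraction`,
#'   `artefact_baseline`, `artefact_post`, `aai_reason`).
#' @export
extract_features <- function(trials, artefact_threshold = 100) {
  stopifnot(inherits(trials, "trial_set"))
  srate <- attr(trials, "srate")
  t <- trial_time_axis(srate)
  base_win <- baseline_window(attr(trials, "fixation_onset"))

  masks <- purrr::map(trials$signal, detect_artefacts, threshold = artefact_threshold)
  aai_res <- purrr::map2(trials$signal, masks, extract_trial_aai, t = t, srate = srate)
  evoked <- quantify_evoked(trials)
  osc <- quantify_oscillatory(trials)

  tibble::tibble(
    subject = trials$subject,
    side = trials$side,
    arm = trials$arm,
    trial = trials$trial,
    half = trials$half,
    aai = purrr::map_dbl(aai_res, "aai"),
    n1 = evoked$n1,
    n2 = evoked$n2,
    p2 = evoked$p2,
    alpha = osc$alpha,
    beta = osc$beta,
    gamma = osc$gamma,
    rating = trials$rating,
    artefact_fraction = purrr::map_dbl(aai_res, "artefact_fraction"),
    artefact_baseline = purrr::map_lgl(
      masks, ~ any(.x[t >= base_win[1] & t <= base_win[2]])
    ),
    artefact_post = purrr::map_lgl(masks, ~ any(.x[t >= 0 & t <= 1.5])),
    aai_reason = purrr::map_chr(aai_res, "reason")
  )
}

# amplitude window used for evoked-response baseline correction:
# 2,000-2,500 ms after fixation onset
baseline_window <- function(fixation_onset) fixation_onset + c(2.0, 2.5)
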