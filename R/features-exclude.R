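#' Apply the preregistered data-exclusion criteria
#'
#' Flags trials and subjects according to the study's exclusion rules:
#' (1) trials with more than 50% of regulation-period epochs rejected for
#' artefacts are dropped from all analyses; (2) trials with a missing or
#' invalid pain rating (outside 0--100) are dropped from all analyses;
#' (3) subjects with fewer than `min_trials` surviving trials in any
#' condition are dropped entirely; (4) subjects flagged for focusing on
#' the wrong hand are dropped entirely. In addition, trials whose
#' artefacts fall in the baseline window or in the 1,500 ms post-stimulus
#' interval are dropped from the evoked/oscillatory features only (they
#' remain usable for the trial asymmetry).
#'
#' @param features a FeatureTable from [extract_features()]; may carry a
#'   logical `wrong_hand` column (per subject).
#' @param min_trials minimum surviving trials per condition (default 10).
#' @return the input tibble with added columns `included` (primary
#'   analyses), `included_erp` (evoked/oscillatory features), and
#'   `reason` (first matching exclusion code, NA when included).
#' @export
apply_exclusions <- function(features, min_trials = 10) {
  req <- c("subject", "side", "arm", "rating", "artefact_fraction")
  stopifnot(all(req %in% names(features)))
  f <- features
  if (!"wrong_hand" %in% names(f)) f$wrong_hand <- FALSE
  if (!"artefact_baseline" %in% names(f)) f$artefact_baseline <- FALSE
  if (!"artefact_post" %in% names(f)) f$artefact_post <- FALSE

  bad_artefact <- f$artefact_fraction > 0.5
  bad_rating <- is.na(f$rating) | f$rating < 0 | f$rating > 100
  trial_ok <- !bad_artefact & !bad_rating

  # subject-level rules act on trials surviving the trial-level rules
  counts <- tibble::as_tibble(f) |>
    dplyr::mutate(.ok = trial_ok) |>
    dplyr::group_by(.data$subject, .data$side, .data$arm) |>
    dplyr::summarise(n_ok = sum(.ok), .groups = "drop") |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(min_ok = min(.data$n_ok), .groups = "drop")
  few <- counts$subject[counts$min_ok < min_trials]
  subj_few <- f$subject %in% few
  subj_hand <- f$wrong_hand

  f$included <- trial_ok & !subj_few & !subj_hand
  f$included_erp <- f$included & !f$artefact_baseline & !f$artefact_post
  f$reason <- dplyr::case_when(
    subj_hand ~ "wrong_hand",
    bad_artefact ~ "artefact_rate",
    bad_rating ~ "invalid_rating",
    subj_few ~ "too_few_trials",
    .default = NA_character_
  )
  f
}

#' Artefact and blinding control indices
#'
#' Normalized verum-sham difference used for the per-subject control
#' analyses: `(verum - sham) / (verum + sham)`, computed per side (ART or
#' ALT). With rejected-trial counts this is the artefact index (AI); with
#' average blinding scores it is the blinding index (BI).
#'
#' @param verum,sham nonnegative numeric vectors (counts or scores).
#' @return numeric vector in `[-1, 1]`; `NA` (with a warning) where both
#'   inputs are zero and the index is undefined.
#' @examples
#' control_index(3, 1) # 0.5
#' control_index(80, 40) # 1/3
#' @export
control_index <- function(verum, sham) {
  stopifnot(length(verum) == length(sham))
  denom <- verum + sham
  out <- ifelse(denom == 0, NA_real_, (verum - sham) / denom)
  if (any(denom == 0)) {
    warning("zero denominator: control index undefined for some entries")
  }
  out
}
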