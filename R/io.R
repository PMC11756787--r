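#' Write a trial set to a plain-text directory store
#'
#' Stores each trial's EEG as a tab-separated samples x channels array,
#' a JSON sidecar with the montage (channel names, sampling rate, units,
#' time axis), and a BIDS-style `events.tsv` with one row per event
#' (fixation, stimulus, rating) carrying the trial identifiers.
#'
#' @param trials a `trial_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial_set <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  srate <- attr(trials, "srate")
  sidecar <- list(
    channels = attr(trials, "channels"),
    sampling_rate = srate,
    units = "microvolt",
    t_start = attr(trials, "t_start"),
    fixation_onset = attr(trials, "fixation_onset"),
    stim_onset = attr(trials, "stim_onset")
  )
  jsonlite::write_json(sidecar, file.path(dir, "recording.json"),
    auto_unbox = TRUE, digits = NA
  )
  ids <- sprintf(
    "sub-%02d_%s_%s_trial-%03d",
    trials$subject, trials$side, trials$arm, trials$trial
  )
  for (i in seq_len(nrow(trials))) {
    mat <- t(trials$signal[[i]])
    colnames(mat) <- rownames(trials$signal[[i]])
    readr::write_tsv(tibble::as_tibble(mat),
      file.path(dir, paste0(ids[i], "_eeg.tsv")),
      progress = FALSE
    )
  }
  events <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tibble::tibble(
      onset = c(
        attr(trials, "fixation_onset"), attr(trials, "stim_onset"), 3
      ),
      duration = c(3, 0.004, 0),
      trial_type = c("fixation", "stimulus", "rating"),
      rating = c(NA, NA, trials$rating[i]),
      subject = trials$subject[i],
      side = trials$side[i],
      arm = trials$arm[i],
      trial = trials$trial[i],
      file = paste0(ids[i], "_eeg.tsv")
    )
  })
  readr::write_tsv(events, file.path(dir, "events.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param dir directory containing `recording.json`, `events.tsv`, and
#'   the per-trial arrays.
#' @return a `trial_set` (without feedback traces).
#' @export
read_trial_set <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "recording.json"),
    simplifyVector = TRUE
  )
  events <- readr::read_tsv(file.path(dir, "events.tsv"),
    show_col_types = FALSE, progress = FALSE
  )
  trials <- events |>
    dplyr::group_by(.data$subject, .data$side, .data$arm, .data$trial, .data$file) |>
    dplyr::summarise(
      rating = .data$rating[.data$trial_type == "rating"], .groups = "drop"
    )
  nt_half <- ceiling(max(trials$trial) / 2)
  trials$half <- ifelse(trials$trial <= nt_half, 1L, 2L)
  trials$signal <- purrr::map(trials$file, function(f) {
    mat <- t(as.matrix(readr::read_tsv(file.path(dir, f),
      show_col_types = FALSE, progress = FALSE
    )))
    mat
  })
  trials$file <- NULL
  cfg <- list(
    sampling_rate = sidecar$sampling_rate,
    channel_names = sidecar$channels
  )
  new_trial_set(trials, cfg)
}

#' Write and read a feedback trace
#'
#' Feedback traces are exchanged as tab-separated time series with
#' columns `t`, `aai`, `faai`, `c`, the format used for yoked replay.
#'
#' @param trace an `aai_series` tibble (from [run_feedback_loop()]).
#' @param path file path.
#' @return `path` invisibly (write); tibble (read).
#' @export
write_feedback_trace <- function(trace, path) {
  stopifnot(all(c("t", "aai", "faai") %in% names(trace)))
  readr::write_tsv(tibble::as_tibble(trace), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feedback_trace
#' @export
read_feedback_trace <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tibble::new_tibble(out, class = "aai_series")
}

#' Write and read a feature table
#'
#' @param features FeatureTable tibble.
#' @param path file path (tab-separated values, one row per trial).
#' @return `path` invisibly (write); tibble (read).
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read and write 8-bit gray-scale PNG images
#'
#' Thin wrappers used for the feedback image pipeline; color images are
#' converted to gray by channel averaging. Requires the `png` package.
#'
#' @param path file path.
#' @param image numeric matrix with values in `[0, 1]` (clipped on
#'   write).
#' @return numeric matrix in `[0, 1]` (read); `path` invisibly (write).
#' @export
read_gray_png <- function(path) {
  rlang::check_installed("png")
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname read_gray_png
#' @export
write_gray_png <- function(image, path) {
  rlang::check_installed("png")
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
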