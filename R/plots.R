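#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a feedback trace
#'
#' Shows the raw and smoothed asymmetry index over the regulation period
#' and, when present, the visibility of the feedback image.
#'
#' @param object an `aai_series` (from [smooth_aai()] or
#'   [run_feedback_loop()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.aai_series <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(-"t", names_to = "series", values_to = "value") |>
    dplyr::mutate(series = dplyr::recode(.data$series,
      aai = "raw AAI", faai = "smoothed AAI", c = "visibility"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = NULL, colour = NULL,
      title = "Neurofeedback trace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the operating characteristics of a sequential design
#'
#' Bar chart of the five terminal categories of an SBF+maxN simulation
#' (boundary stops and Nmax categories).
#'
#' @param object an `sbf_design` (from [simulate_sbf_maxn()]).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sbf_design <- function(object, ...) {
  df <- tidy(object)
  df$outcome <- factor(df$outcome, levels = df$outcome)
  ggplot2::ggplot(df, ggplot2::aes(.data$outcome, .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(
      x = NULL, y = "simulated studies",
      title = sprintf(
        "SBF+maxN operating characteristics (d = %.2f, mean stop n = %.0f)",
        object$d_true, object$mean_stop_n
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot mediation path estimates
#'
#' Point-interval plot of the group-level path coefficients of a
#' multilevel mediation fit.
#'
#' @param object a `mediation_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- object$paths
  df$path <- factor(df$path, levels = rev(df$path))
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$path)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$ci_lower, xmax = .data$ci_upper,
        colour = .data$present)
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"), guide = "none"
    ) +
    ggplot2::labs(
      x = "posterior median and 95% interval", y = NULL,
      title = "Multilevel mediation paths"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-subject condition averages
#'
#' Boxplots of the 8 condition cells (side x arm x half) across
#' subjects, the raw material of the adaptive hypothesis pipeline.
#'
#' @param avgs condition averages from [condition_averages()].
#' @param outcome axis label (default "AAI").
#' @return a ggplot.
#' @export
plot_condition_averages <- function(avgs, outcome = "AAI") {
  df <- avgs |>
    dplyr::mutate(
      cell = paste0(.data$side, "_", .data$arm),
      half = factor(.data$half, labels = c("1st half", "2nd half"))
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$cell, .data$value, fill = .data$half)) +
    ggplot2::geom_boxplot(outlier.size = 0.7, position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = outcome, fill = NULL) +
    ggplot2::theme_minimal()
}
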