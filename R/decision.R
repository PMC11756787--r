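#' Per-subject condition averages
#'
#' Collapses a single-trial FeatureTable into the 8 per-subject cell
#' means (ART/ALT x verum/sham x first/second half of trials) that the
#' adaptive hypothesis pipeline analyzes.
#'
#' @param features FeatureTable (e.g. from [extract_features()] or
#'   [simulate_features()]); rows already excluded by
#'   [apply_exclusions()] can be removed beforehand via the `included`
#'   flag.
#' @param outcome name of the feature column to average (e.g. `"aai"`,
#'   `"rating"`, `"n2"`).
#' @return tibble with columns `subject`, `side`, `arm`, `half`, `value`.
#' @export
condition_averages <- function(features, outcome = "aai") {
  stopifnot(all(c("subject", "side", "arm", "half") %in% names(features)))
  if (!outcome %in% names(features)) stop("no column called '", outcome, "'")
  features |>
    dplyr::group_by(.data$subject, .data$side, .data$arm, .data$half) |>
    dplyr::summarise(
      value = mean(.data[[outcome]], na.rm = TRUE), .groups = "drop"
    )
}

#' Classify an evidence-category triple into a result pattern
#'
#' Pure function implementing the preregistered interpretation rules:
#' with attention evidence "for", the time and neurofeedback categories
#' select pattern 1 (time and neurofeedback), pattern 2 (time only),
#' pattern 3 (neurofeedback only) or pattern 4 (attention only); evidence
#' against the attention effect means evidence for the absence of
#' up-/down-regulation; anything else is inconclusive.
#'
#' @param time,nf,att evidence categories
#'   (`"for"`/`"against"`/`"inconclusive"`).
#' @return one of `"pattern1"`, `"pattern2"`, `"pattern3"`, `"pattern4"`,
#'   `"absence"`, `"inconclusive"`.
#' @export
classify_pattern <- function(time, nf, att) {
  cats <- c("for", "against", "inconclusive")
  stopifnot(time %in% cats, nf %in% cats, att %in% cats)
  if (att == "for") {
    if (time == "for" && nf == "for") return("pattern1")
    if (time == "for") return("pattern2")
    if (nf == "for") return("pattern3")
    return("pattern4")
  }
  if (att == "against") return("absence")
  "inconclusive"
}

# paired one-sided test with the decision pipeline's normality gate
pipeline_test <- function(diffs, direction, test, seed = NULL) {
  if (test == "auto") {
    test <- if (stats::shapiro.test(diffs)$p.value < 0.05) "wilcoxon" else "t"
  }
  if (test == "t") {
    bf_paired_onesided(diffs, direction = direction)
  } else {
    bf_signed_rank_onesided(diffs, direction = direction, seed = seed)
  }
}

# "for" if any sub-test is for, "against" if all are against, else inconclusive
combine_categories <- function(cats) {
  if (any(cats == "for")) return("for")
  if (all(cats == "against")) return("against")
  "inconclusive"
}

cell_value <- function(avgs, side, arm = NULL, half = NULL) {
  x <- avgs[avgs$side == side, ]
  if (!is.null(arm)) x <- x[x$arm == arm, ]
  if (!is.null(half)) x <- x[x$half %in% half, ]
  out <- stats::aggregate(value ~ subject, data = x, FUN = mean)
  out$value[order(out$subject)]
}

#' Adaptive hypothesis pipeline for the asymmetry index
#'
#' Runs the preregistered decision sequence on per-subject condition
#' averages of the AAI. The time contrasts (second vs first half, ART up
#' / ALT down, verum conditions) decide whether subsequent analyses use
#' second-half or all-trial averages; the neurofeedback contrasts (verum
#' vs sham per side) decide whether the attention contrast is evaluated
#' on sham cells only or on verum/sham-averaged cells; the resulting
#' category triple is classified into a result pattern.
#'
#' @param avgs condition averages from [condition_averages()] (or
#'   [simulate_condition_averages()]); subjects with incomplete cells are
#'   dropped with a message.
#' @param test `"auto"` (Shapiro--Wilk gate at alpha = 0.05), `"t"`, or
#'   `"wilcoxon"`.
#' @param seed seed forwarded to the signed-rank sampler when used.
#' @return `pipeline_outcome` object: list with `tests` (tibble of every
#'   sub-test: hypothesis, side, direction, bf10, category), `categories`
#'   (time/nf/att), `flags` (`use_second_half`, `use_sham_only`),
#'   `pattern`, and `n` subjects.
#' @export
run_aai_pipeline <- function(avgs, test = c("auto", "t", "wilcoxon"),
                             seed = NULL) {
  test <- match.arg(test)
  avgs <- complete_subjects(avgs)
  n <- length(unique(avgs$subject))

  # H1.1: time effect on verum conditions (ART up, ALT down)
  t_a <- pipeline_test(
    cell_value(avgs, "ART", "verum", 2) - cell_value(avgs, "ART", "verum", 1),
    "greater", test, seed
  )
  t_b <- pipeline_test(
    cell_value(avgs, "ALT", "verum", 2) - cell_value(avgs, "ALT", "verum", 1),
    "less", test, seed
  )
  time_cat <- combine_categories(classify_evidence(c(t_a$bf10, t_b$bf10)))
  halves <- if (time_cat == "for") 2 else 1:2

  # H1.2: neurofeedback effect (verum vs sham per side)
  nf_a <- pipeline_test(
    cell_value(avgs, "ART", "verum", halves) - cell_value(avgs, "ART", "sham", halves),
    "greater", test, seed
  )
  nf_b <- pipeline_test(
    cell_value(avgs, "ALT", "verum", halves) - cell_value(avgs, "ALT", "sham", halves),
    "less", test, seed
  )
  nf_cat <- combine_categories(classify_evidence(c(nf_a$bf10, nf_b$bf10)))
  sham_only <- nf_cat == "for"

  # H1.3: attention effect (sham cells if a neurofeedback effect was found)
  arms <- if (sham_only) "sham" else NULL
  att <- pipeline_test(
    cell_value(avgs, "ART", arms, halves) - cell_value(avgs, "ALT", arms, halves),
    "greater", test, seed
  )
  att_cat <- classify_evidence(att$bf10)

  tests <- dplyr::bind_rows(
    cbind(hypothesis = "time", side = c("ART", "ALT"),
      dplyr::bind_rows(tidy(t_a), tidy(t_b))),
    cbind(hypothesis = "neurofeedback", side = c("ART", "ALT"),
      dplyr::bind_rows(tidy(nf_a), tidy(nf_b))),
    cbind(hypothesis = "attention", side = "ART-ALT", tidy(att))
  )
  structure(
    list(
      tests = tibble::as_tibble(tests),
      categories = c(time = time_cat, nf = nf_cat, att = att_cat),
      flags = c(use_second_half = time_cat == "for", use_sham_only = sham_only),
      pattern = classify_pattern(time_cat, nf_cat, att_cat),
      outcome = "aai",
      n = n
    ),
    class = "pipeline_outcome"
  )
}

#' Adaptive hypothesis pipeline for pain ratings and brain responses
#'
#' Repeats the decision sequence for an outcome that is inversely related
#' to the asymmetry index (pain ratings, evoked and oscillatory brain
#' responses): the directions of all pairwise contrasts are reversed and
#' time effects are not tested. Data-selection decisions (second half vs
#' all trials; whether a neurofeedback effect on the AAI was found) are
#' inherited from the AAI pipeline run, as is the time category used in
#' the pattern classification.
#'
#' @param avgs condition averages of the outcome.
#' @param aai_outcome the `pipeline_outcome` of [run_aai_pipeline()].
#' @param attention_data `"sham"` to contrast sham cells when an AAI
#'   neurofeedback effect was found (as for pain ratings), or `"diff"` to
#'   contrast verum-minus-sham differences between sides (as specified
#'   for brain responses); ignored (verum/sham-averaged cells) when no
#'   AAI neurofeedback effect was found.
#' @inheritParams run_aai_pipeline
#' @return `pipeline_outcome` (see [run_aai_pipeline()]).
#' @export
run_outcome_pipeline <- function(avgs, aai_outcome,
                                 attention_data = c("sham", "diff"),
                                 test = c("auto", "t", "wilcoxon"),
                                 seed = NULL) {
  attention_data <- match.arg(attention_data)
  test <- match.arg(test)
  stopifnot(inherits(aai_outcome, "pipeline_outcome"))
  avgs <- complete_subjects(avgs)
  n <- length(unique(avgs$subject))

  halves <- if (aai_outcome$flags[["use_second_half"]]) 2 else 1:2
  aai_nf_found <- aai_outcome$flags[["use_sham_only"]]

  # neurofeedback effect, reversed directions (verum < sham for ART, > for ALT)
  nf_a <- pipeline_test(
    cell_value(avgs, "ART", "verum", halves) - cell_value(avgs, "ART", "sham", halves),
    "less", test, seed
  )
  nf_b <- pipeline_test(
    cell_value(avgs, "ALT", "verum", halves) - cell_value(avgs, "ALT", "sham", halves),
    "greater", test, seed
  )
  nf_cat <- combine_categories(classify_evidence(c(nf_a$bf10, nf_b$bf10)))

  # attention effect, reversed direction (ART < ALT)
  if (aai_nf_found && attention_data == "diff") {
    contrast <-
      (cell_value(avgs, "ART", "verum", halves) - cell_value(avgs, "ART", "sham", halves)) -
      (cell_value(avgs, "ALT", "verum", halves) - cell_value(avgs, "ALT", "sham", halves))
  } else {
    arms <- if (aai_nf_found) "sham" else NULL
    contrast <- cell_value(avgs, "ART", arms, halves) -
      cell_value(avgs, "ALT", arms, halves)
  }
  att <- pipeline_test(contrast, "less", test, seed)
  att_cat <- classify_evidence(att$bf10)

  time_cat <- aai_outcome$categories[["time"]]
  tests <- dplyr::bind_rows(
    cbind(hypothesis = "neurofeedback", side = c("ART", "ALT"),
      dplyr::bind_rows(tidy(nf_a), tidy(nf_b))),
    cbind(hypothesis = "attention", side = "ART-ALT", tidy(att))
  )
  structure(
    list(
      tests = tibble::as_tibble(tests),
      categories = c(time = time_cat, nf = nf_cat, att = att_cat),
      flags = c(
        use_second_half = aai_outcome$flags[["use_second_half"]],
        use_sham_only = aai_nf_found
      ),
      pattern = classify_pattern(time_cat, nf_cat, att_cat),
      outcome = "outcome",
      n = n
    ),
    class = "pipeline_outcome"
  )
}

# keep only subjects with all 8 cells present
complete_subjects <- function(avgs) {
  stopifnot(all(c("subject", "side", "arm", "half", "value") %in% names(avgs)))
  counts <- avgs |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n_cells = dplyr::n_distinct(
      paste(.data$side, .data$arm, .data$half)
    ), .groups = "drop")
  incomplete <- counts$subject[counts$n_cells < 8]
  incomplete <- union(incomplete, setdiff(unique(avgs$subject), counts$subject))
  if (length(incomplete)) {
    message(
      "dropping ", length(incomplete),
      " subject(s) with incomplete condition cells"
    )
    avgs <- avgs[!avgs$subject %in% incomplete, ]
  }
  if (!nrow(avgs)) stop("no complete subjects")
  avgs
}

#' @export
print.pipeline_outcome <- function(x, ...) {
  cat(sprintf(
    "<pipeline_outcome> %s, n = %d: time %s, neurofeedback %s, attention %s -> %s\n",
    x$outcome, x$n, x$categories[["time"]], x$categories[["nf"]],
    x$categories[["att"]], x$pattern
  ))
  cat(sprintf(
    "  data selection: %s, attention on %s\n",
    if (x$flags[["use_second_half"]]) "second half" else "all trials",
    if (x$flags[["use_sham_only"]]) "sham cells" else "verum/sham average"
  ))
  invisible(x)
}

#' @export
tidy.pipeline_outcome <- function(x, ...) x$tests

#' @export
glance.pipeline_outcome <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    time = x$categories[["time"]],
    nf = x$categories[["nf"]],
    att = x$categories[["att"]],
    pattern = x$pattern,
    use_second_half = x$flags[["use_second_half"]],
    use_sham_only = x$flags[["use_sham_only"]],
    n = x$n
  )
}
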