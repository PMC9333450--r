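#' Area under the growth curve
#'
#' Integrates background-subtracted OD600 over time with the trapezoid
#' rule, restricted to the first `window_hours` hours. Negative
#' background-subtracted values are not clamped: instrument noise can dip
#' below background and clamping would bias the area upward.
#'
#' @param time_min Timepoints in minutes, nondecreasing.
#' @param od OD600 readings, same length.
#' @param background OD600 value subtracted before integration; defaults
#'   to the first in-window reading of the well.
#' @param window_hours Integration window in hours (default 24).
#' @return The area in OD x hours.
#' @examples
#' t <- seq(0, 24 * 60, by = 15)
#' augc(t, rep(0.3, length(t)), background = 0.05) # 0.25 * 24 = 6
#' @export
augc <- function(time_min, od, background = NULL, window_hours = 24) {
  if (length(time_min) != length(od)) {
    abort("`time_min` and `od` must have the same length.", class = "ndsynergy_invalid_parameter")
  }
  if (is.unsorted(time_min)) {
    abort("`time_min` must be nondecreasing.", class = "ndsynergy_invalid_parameter")
  }
  keep <- time_min <= window_hours * 60
  t_h <- time_min[keep] / 60
  y <- od[keep]
  if (length(t_h) < 2) {
    abort("Need at least 2 readings inside the window.", class = "ndsynergy_insufficient_data")
  }
  if (is.null(background)) background <- y[1]
  y <- y - background
  sum(diff(t_h) * (y[-1] + y[-length(y)]) / 2)
}

#' Maximum growth rate
#'
#' The maximum slope of a five-point moving average of log(OD600 -
#' background) versus time; natural log, so the value is the per-hour
#' exponential rate at the steepest part of the curve. Readings at or
#' below background (log undefined) are dropped before smoothing; the
#' moving-average window is centered and truncated at the series ends.
#'
#' @inheritParams augc
#' @return Maximum slope in 1/hour (natural log scale).
#' @examples
#' t <- seq(0, 600, by = 15)
#' max_growth_rate(t, 0.05 + 0.01 * exp(0.5 * t / 60), background = 0.05)
#' @export
max_growth_rate <- function(time_min, od, background = NULL, window_hours = 24) {
  if (length(time_min) != length(od)) {
    abort("`time_min` and `od` must have the same length.", class = "ndsynergy_invalid_parameter")
  }
  if (is.unsorted(time_min)) {
    abort("`time_min` must be nondecreasing.", class = "ndsynergy_invalid_parameter")
  }
  keep <- time_min <= window_hours * 60
  t_h <- time_min[keep] / 60
  y <- od[keep]
  if (is.null(background)) background <- y[1]
  usable <- y > background
  t_h <- t_h[usable]
  ly <- log(y[usable] - background)
  n <- length(ly)
  if (n < 6) {
    abort("Need at least 6 readings above background for a growth rate.",
          class = "ndsynergy_insufficient_data")
  }
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - 2):min(n, i + 2)
    mean(ly[w])
  }, numeric(1))
  dt <- diff(t_h)
  slopes <- diff(sm) / dt
  max(slopes[is.finite(slopes)])
}

#' Per-well growth measures
#'
#' Computes AUGC and, where enough above-background readings exist, the
#' maximum growth rate, for every well of a long-format readings table.
#'
#' @param readings Tibble with columns `plate`, `well`, `time_min`,
#'   `od600`.
#' @param window_hours Quantification window in hours.
#' @param background Either `NULL` (per-well first reading) or a single
#'   OD600 value (e.g. a media-blank estimate) applied to every well.
#' @return A tibble with one row per `(plate, well)` and columns `augc`
#'   (OD x hours) and `max_growth_rate` (1/hour, `NA` when undefined).
#' @export
growth_measures <- function(readings, window_hours = 24, background = NULL) {
  check_columns(readings, c("plate", "well", "time_min", "od600"), "readings")
  readings %>%
    dplyr::group_by(.data$plate, .data$well) %>%
    dplyr::arrange(.data$time_min, .by_group = TRUE) %>%
    dplyr::summarise(
      augc = augc(.data$time_min, .data$od600, background = background,
                  window_hours = window_hours),
      max_growth_rate = tryCatch(
        max_growth_rate(.data$time_min, .data$od600, background = background,
                        window_hours = window_hours),
        ndsynergy_insufficient_data = function(e) NA_real_
      ),
      .groups = "drop"
    )
}

#' Aggregate replicate measures into effectiveness calls
#'
#' Applies the effectiveness rule "measure at most `t`" per condition.
#' With `replicate_rule = "mean"` replicates are averaged before the
#' comparison; `"all"` requires every replicate to pass, `"any"` at least
#' one. The comparison is inclusive: a measure exactly at the threshold is
#' effective.
#'
#' @param measures Tibble with a `value` column plus any condition
#'   identifier columns; one row per replicate measure.
#' @param threshold The threshold `t`, in the measure's units.
#' @param replicate_rule `"mean"` (default), `"all"`, or `"any"`.
#' @param by Character vector of columns identifying a condition
#'   (defaults to all columns except `value` and `replicate`).
#' @return A tibble with one row per condition: aggregated `value`,
#'   `n_replicates`, and logical `effective`.
#' @examples
#' m <- tibble::tibble(cond = c("a", "a"), replicate = 1:2, value = c(1, 3))
#' call_effectiveness(m, threshold = 2.5)
#' @export
call_effectiveness <- function(measures, threshold,
                               replicate_rule = c("mean", "all", "any"),
                               by = NULL) {
  replicate_rule <- tryCatch(match.arg(replicate_rule), error = function(e) {
    abort(sprintf("Unknown replicate rule '%s'.", replicate_rule[1]),
          class = "ndsynergy_invalid_parameter")
  })
  stopifnot_scalar_number(threshold, "threshold")
  if (!"value" %in% names(measures)) {
    abort("`measures` must have a `value` column.", class = "ndsynergy_invalid_parameter")
  }
  if (is.null(by)) by <- setdiff(names(measures), c("value", "replicate"))
  measures %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) %>%
    dplyr::summarise(
      n_replicates = dplyr::n(),
      effective = switch(replicate_rule,
        mean = mean(.data$value) <= threshold,
        all = all(.data$value <= threshold),
        any = any(.data$value <= threshold)
      ),
      value = mean(.data$value),
      .groups = "drop"
    ) %>%
    dplyr::relocate("value", .before = "n_replicates")
}

#' Quantify a screen into an effectiveness table
#'
#' The full growth-quantification step: joins plate-reader readings onto
#' the design by `(plate, well)`, computes the chosen growth measure per
#' well, derives the effectiveness threshold from the drug-free controls
#' (unless an absolute threshold is given), and aggregates replicates into
#' per-condition effective/ineffective calls.
#'
#' @param readings Long-format readings tibble (`plate`, `well`,
#'   `time_min`, `od600`).
#' @param design An [enumerate_nds()] design with plate/well assignments.
#' @param measure `"augc"` (default) or `"max_growth_rate"`.
#' @param window_hours Quantification window (hours).
#' @param threshold Absolute threshold in the measure's units, or `NULL`
#'   to use `threshold_frac` of the mean control measure.
#' @param threshold_frac Fraction of the mean drug-free control measure
#'   used as threshold when `threshold` is `NULL` (default 0.1, i.e.
#'   effectiveness means growth reduced to at most 10% of control).
#' @param replicate_rule Replicate aggregation rule, see
#'   [call_effectiveness()].
#' @param background See [growth_measures()].
#' @return A tibble of class `effectiveness_table`: one row per condition
#'   (`subset`, `step`, `ratio`, per-drug concentrations) with `value`,
#'   `n_replicates`, `effective`. The threshold, measure, rule and panel
#'   are carried as attributes.
#' @export
quantify_effectiveness <- function(readings, design,
                                   measure = c("augc", "max_growth_rate"),
                                   window_hours = 24,
                                   threshold = NULL, threshold_frac = 0.1,
                                   replicate_rule = "mean",
                                   background = NULL) {
  measure <- match.arg(measure)
  panel <- design_panel(design)
  if (is.null(panel)) {
    abort("`design` must carry its panel (use enumerate_nds()).",
          class = "ndsynergy_invalid_parameter")
  }
  per_well <- growth_measures(readings, window_hours = window_hours,
                              background = background)
  per_well$value <- per_well[[measure]]
  joined <- dplyr::inner_join(
    tibble::as_tibble(design), per_well[, c("plate", "well", "value")],
    by = c("plate", "well")
  )
  if (nrow(joined) < nrow(design)) {
    abort(sprintf("Readings missing for %d design wells.",
                  nrow(design) - nrow(joined)),
          class = "ndsynergy_incomplete_design")
  }

  if (is.null(threshold)) {
    ctrl <- joined$value[joined$subset == ""]
    if (length(ctrl) == 0) {
      abort("No drug-free control wells; supply an absolute `threshold`.",
            class = "ndsynergy_invalid_parameter")
    }
    threshold <- threshold_frac * mean(ctrl)
  }

  conds <- call_effectiveness(
    joined[, c("subset", "step", "ratio", panel$asm_code, "replicate", "value")],
    threshold = threshold, replicate_rule = replicate_rule
  )
  structure(conds,
            class = c("effectiveness_table", class(conds)),
            panel = panel,
            measure = measure,
            threshold = threshold,
            replicate_rule = replicate_rule)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "ndsynergy_parse_error")
  }
  invisible(df)
}
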