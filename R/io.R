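# File schemas. All delimited files are comma-separated UTF-8 with a header
# row, decimal points, and unquoted numerics; concentrations are written as
# decimal text at full round-trip precision so a write/read cycle is exact.

#' Read / write plate-reader readings
#'
#' Long-format OD600 time series: one row per reading with columns
#' `plate`, `well`, `time_min`, `od600`.
#'
#' @param path File path.
#' @return `read_readings()` returns a tibble; writers return `path`
#'   invisibly.
#' @export
read_readings <- function(path) {
  df <- read_checked(path, c("plate", "well", "time_min", "od600"))
  df$time_min <- as.numeric(df$time_min)
  df$od600 <- as.numeric(df$od600)
  df
}

#' @rdname read_readings
#' @param readings Tibble as returned by [read_readings()] or
#'   [synthesize_readings()].
#' @export
write_readings <- function(readings, path) {
  check_columns(readings, c("plate", "well", "time_min", "od600"), "readings")
  readr::write_csv(readings, path)
  invisible(path)
}

#' Read / write an NDS design
#'
#' One row per design point: `plate`, `well`, `replicate`, `subset`
#' (semicolon-joined drug codes, empty for drug-free controls),
#' `step_index`, `ratio`, then one concentration column per panel drug
#' (ug/mL). Unknown extra columns are preserved.
#'
#' @param path File path.
#' @param panel The [drug_panel()] the design was built for.
#' @return `read_design()` returns an `nds_design` tibble.
#' @export
read_design <- function(path, panel) {
  df <- read_checked(path, c("plate", "well", "replicate", "subset",
                             "step_index", "ratio", panel$asm_code))
  df$subset[is.na(df$subset)] <- ""
  out <- tibble::tibble(
    plate = as.character(df$plate),
    well = as.character(df$well),
    replicate = as.integer(df$replicate),
    subset = df$subset,
    step = as.integer(df$step_index),
    ratio = as.numeric(df$ratio)
  )
  for (code in panel$asm_code) out[[code]] <- as.numeric(df[[code]])
  extra <- setdiff(names(df), c("plate", "well", "replicate", "subset",
                                "step_index", "ratio", panel$asm_code))
  for (col in extra) out[[col]] <- df[[col]]
  structure(out,
            class = c("nds_design", class(out)),
            panel = panel,
            replicates = max(out$replicate))
}

#' @rdname read_design
#' @param design An [enumerate_nds()] design.
#' @export
write_design <- function(design, path) {
  df <- tibble::as_tibble(design)
  df <- dplyr::rename(df, step_index = "step")
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read / write an effectiveness table
#'
#' One row per condition: `subset`, `step_index`, `ratio`, per-drug
#' concentrations, `value` (the growth measure), `n_replicates`,
#' `effective`.
#'
#' @param path File path.
#' @param panel The [drug_panel()].
#' @return `read_effectiveness()` returns an `effectiveness_table`.
#' @export
read_effectiveness <- function(path, panel) {
  df <- read_checked(path, c("subset", "step_index", "ratio", panel$asm_code,
                             "value", "n_replicates", "effective"))
  df$subset[is.na(df$subset)] <- ""
  out <- tibble::tibble(
    subset = df$subset,
    step = as.integer(df$step_index),
    ratio = as.numeric(df$ratio)
  )
  for (code in panel$asm_code) out[[code]] <- as.numeric(df[[code]])
  out$value <- as.numeric(df$value)
  out$n_replicates <- as.integer(df$n_replicates)
  out$effective <- as.logical(df$effective)
  structure(out,
            class = c("effectiveness_table", class(out)),
            panel = panel)
}

#' @rdname read_effectiveness
#' @param effectiveness An effectiveness table.
#' @export
write_effectiveness <- function(effectiveness, path) {
  df <- tibble::as_tibble(effectiveness)
  df <- dplyr::rename(df, step_index = "step")
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read / write synergy scores
#'
#' One row per scored subset with all score columns (raw and log2), the
#' classification, the witness condition, and the normalization label.
#'
#' @param path File path.
#' @return `read_scores()` returns a tibble.
#' @export
read_scores <- function(path) {
  read_checked(path, c("subset", "size", "meci", "tss", "ess",
                       "fici_diagonal_bound", "classification",
                       "normalization_label"))
}

#' @rdname read_scores
#' @param scores A [score_all_subsets()] result.
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(tibble::as_tibble(scores), path, na = "NA")
  invisible(path)
}

#' Write a run manifest
#'
#' Records every parameter of a pipeline run (paths, design parameters,
#' seed, measure and threshold settings, closure rule) as JSON so that
#' deterministic stages can be re-run bit-identically.
#'
#' @param config Named list of parameters.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

read_checked <- function(path, required) {
  if (!file.exists(path)) {
    abort(sprintf("File '%s' does not exist.", path), class = "ndsynergy_parse_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("File '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "ndsynergy_parse_error")
  }
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("File '%s' has malformed rows (first at line %d, column %s).",
                  path, probs$row[1], probs$col[1]),
          class = "ndsynergy_parse_error")
  }
  df
}
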