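#' Construct a drug panel
#'
#' A drug panel holds the `d` antibiotics of a screen together with the
#' per-drug concentrations used to normalize them onto a common scale: the
#' experimentally determined MIC, the species-level susceptible breakpoint
#' (e.g. EUCAST), or a custom clinically motivated dose. All synergy scores
#' downstream are relative to this normalization, so the choice is recorded
#' on the panel and propagated into every output.
#'
#' @param name Character vector of full drug names (unique).
#' @param asm_code Character vector of short drug codes (ASM abbreviations;
#'   unique). Used as column names for concentrations and as subset labels.
#' @param mic Numeric vector of minimum inhibitory concentrations in ug/mL
#'   (> 0).
#' @param breakpoint Numeric vector of susceptible breakpoints in ug/mL
#'   (> 0, or `NA` where no breakpoint is defined).
#' @param normalization Either one of `"breakpoint"`, `"MIC"`, `"custom"`,
#'   or (with `"custom"`) supply `custom` values. The default uses the
#'   breakpoint where available and falls back to the MIC.
#' @param custom Optional numeric vector of custom normalization
#'   concentrations in ug/mL (> 0); required when
#'   `normalization = "custom"`.
#'
#' @return A tibble of class `drug_panel` with columns `name`, `asm_code`,
#'   `mic`, `breakpoint`, `normalization` (the numeric constant N_i in
#'   ug/mL), and an attribute `normalization_label`.
#' @examples
#' drug_panel(
#'   name = c("Ampicillin", "Aztreonam"),
#'   asm_code = c("AMP", "ATM"),
#'   mic = c(16, 0.25),
#'   breakpoint = c(8, 1)
#' )
#' @export
drug_panel <- function(name, asm_code, mic, breakpoint = NA_real_,
                       normalization = c("breakpoint", "MIC", "custom"),
                       custom = NULL) {
  normalization <- match.arg(normalization)
  d <- length(name)
  if (d < 1) abort("A panel needs at least one drug.", class = "ndsynergy_invalid_parameter")
  breakpoint <- rep_len(as.numeric(breakpoint), d)
  if (anyDuplicated(name) || anyDuplicated(asm_code)) {
    abort("Drug names and codes must be unique.", class = "ndsynergy_invalid_parameter")
  }
  if (any(!is.finite(mic)) || any(mic <= 0)) {
    abort("All MICs must be finite and > 0.", class = "ndsynergy_invalid_parameter")
  }
  if (any(!is.na(breakpoint) & breakpoint <= 0)) {
    abort("Breakpoints, where given, must be > 0.", class = "ndsynergy_invalid_parameter")
  }

  n_i <- switch(normalization,
    MIC = mic,
    breakpoint = ifelse(is.na(breakpoint), mic, breakpoint),
    custom = {
      if (is.null(custom)) {
        abort("`custom` normalization values are required when normalization = \"custom\".",
              class = "ndsynergy_invalid_parameter")
      }
      as.numeric(rep_len(custom, d))
    }
  )
  if (any(!is.finite(n_i)) || any(n_i <= 0)) {
    abort("Normalization constants must be finite and > 0.",
          class = "ndsynergy_invalid_parameter")
  }
  label <- if (normalization == "breakpoint" && any(is.na(breakpoint))) {
    "breakpoint (MIC fallback)"
  } else {
    normalization
  }

  out <- tibble::tibble(
    name = as.character(name),
    asm_code = as.character(asm_code),
    mic = as.numeric(mic),
    breakpoint = breakpoint,
    normalization = n_i
  )
  structure(out,
            class = c("drug_panel", class(out)),
            normalization_label = label)
}

#' Normalization label of a panel
#'
#' @param panel A [drug_panel()].
#' @return The label ("MIC", "breakpoint", or "custom") recorded when the
#'   panel was built.
#' @export
normalization_label <- function(panel) {
  attr(panel, "normalization_label") %||% "custom"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Eight-antibiotic E. coli reference panel
#'
#' The eight antibiotics of the wild-type *E. coli* MG-1655 screen, with
#' EUCAST susceptible breakpoints and experimentally determined MICs
#' (ug/mL). Useful for examples and for reproducing design arithmetic.
#'
#' @inheritParams drug_panel
#' @return A [drug_panel()] with 8 drugs.
#' @examples
#' ecoli_panel("MIC")
#' @export
ecoli_panel <- function(normalization = c("breakpoint", "MIC")) {
  normalization <- match.arg(normalization)
  drug_panel(
    name = c("Ampicillin", "Aztreonam", "Ceftazidime", "Chloramphenicol",
             "Ciprofloxacin", "Gentamicin", "Trimethoprim", "Tobramycin"),
    asm_code = c("AMP", "ATM", "CAZ", "CHL", "CIP", "GEN", "TMP", "TOB"),
    breakpoint = c(8, 1, 1, 8, 0.25, 2, 4, 2),
    mic = c(16, 0.25, 0.25, 8, 0.015625, 0.5, 0.25, 0.5),
    normalization = normalization
  )
}

#' Read / write a panel configuration
#'
#' Panels are stored as YAML: a `normalization` label plus a `drugs` list
#' with per-drug `name`, `asm_code`, `mic`, `breakpoint` and (optionally)
#' `normalization` concentration, all in ug/mL.
#'
#' @param path File path.
#' @return `read_panel()` returns a [drug_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$drugs)) {
    abort(sprintf("Panel file '%s' has no `drugs` entry.", path),
          class = "ndsynergy_parse_error")
  }
  drugs <- purrr::map_dfr(cfg$drugs, function(x) {
    tibble::tibble(
      name = x$name,
      asm_code = x$asm_code,
      mic = as.numeric(x$mic),
      breakpoint = if (is.null(x$breakpoint)) NA_real_ else as.numeric(x$breakpoint),
      custom = if (is.null(x$normalization)) NA_real_ else as.numeric(x$normalization)
    )
  })
  label <- cfg$normalization %||% "breakpoint"
  if (label == "custom") {
    drug_panel(drugs$name, drugs$asm_code, drugs$mic, drugs$breakpoint,
               normalization = "custom", custom = drugs$custom)
  } else {
    drug_panel(drugs$name, drugs$asm_code, drugs$mic, drugs$breakpoint,
               normalization = label)
  }
}

#' @rdname read_panel
#' @param panel A [drug_panel()].
#' @export
write_panel <- function(panel, path) {
  label <- normalization_label(panel)
  cfg <- list(
    normalization = if (grepl("^breakpoint", label)) "breakpoint" else label,
    drugs = purrr::pmap(panel, function(name, asm_code, mic, breakpoint,
                                        normalization) {
      x <- list(name = name, asm_code = asm_code, mic = mic)
      if (!is.na(breakpoint)) x$breakpoint <- breakpoint
      if (label == "custom") x$normalization <- normalization
      x
    })
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
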