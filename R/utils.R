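# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data :=
#' @importFrom dplyr %>%
NULL

# Canonical key for a drug subset: ASM codes joined by ";" in panel order.
# "" is the drug-free control.
subset_key <- function(codes, panel) {
  ord <- panel$asm_code[panel$asm_code %in% codes]
  if (length(ord) != length(unique(codes))) {
    abort(paste0(
      "Unknown drug code(s): ",
      paste(setdiff(codes, panel$asm_code), collapse = ", ")
    ), class = "ndsynergy_invalid_parameter")
  }
  paste(ord, collapse = ";")
}

parse_subset <- function(key) {
  if (is.na(key) || !nzchar(key)) character(0) else strsplit(key, ";", fixed = TRUE)[[1]]
}

# All nonempty subsets of the panel's drugs, as keys, ordered by size then
# panel order. d <= 12 keeps this a plain enumeration.
all_subset_keys <- function(panel) {
  codes <- panel$asm_code
  d <- length(codes)
  keys <- unlist(lapply(seq_len(d), function(k) {
    utils::combn(codes, k, FUN = function(s) paste(s, collapse = ";"))
  }))
  keys
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ndsynergy_invalid_parameter")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name),
          class = "ndsynergy_invalid_parameter")
  }
  invisible(x)
}

# log2 that maps NA -> NA without warnings
log2_or_na <- function(x) ifelse(is.na(x), NA_real_, log2(x))
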