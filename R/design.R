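#' Build a dilution ladder
#'
#' The ladder is the ordered set of normalized concentration ratios
#' `c_1 > c_2 > ... > c_s` at which every drug subset is tested on its
#' diagonal. Ratios are unitless multiples of each drug's normalization
#' constant; the default two-fold ladder starting at 1 reproduces the usual
#' serial-dilution gradient.
#'
#' @param top_ratio Highest ratio `c_1` (> 0).
#' @param dilution_factor Fold change between consecutive steps (> 1).
#' @param steps Number of nonzero ratios (>= 1).
#' @return A tibble of class `dilution_ladder` with columns `step` and
#'   `ratio`, strictly decreasing in `ratio`, and a `dilution_factor`
#'   attribute.
#' @examples
#' build_ladder(1, 2, 10)
#' @export
build_ladder <- function(top_ratio = 1, dilution_factor = 2, steps = 10) {
  stopifnot_scalar_number(top_ratio, "top_ratio", positive = TRUE)
  stopifnot_scalar_number(dilution_factor, "dilution_factor")
  stopifnot_scalar_number(steps, "steps")
  if (dilution_factor <= 1) {
    abort("`dilution_factor` must be > 1.", class = "ndsynergy_invalid_parameter")
  }
  if (steps < 1 || steps != round(steps)) {
    abort("`steps` must be a positive integer.", class = "ndsynergy_invalid_parameter")
  }
  out <- tibble::tibble(
    step = seq_len(steps),
    ratio = top_ratio * dilution_factor^(-(seq_len(steps) - 1))
  )
  structure(out,
            class = c("dilution_ladder", class(out)),
            dilution_factor = dilution_factor)
}

ladder_ratios <- function(ladder) {
  if (is.data.frame(ladder)) ladder$ratio else as.numeric(ladder)
}

#' Well-count accounting for an NDS screen
#'
#' The diagonal design's published accounting counts `m` wells for each of
#' the `2^d` drug subsets (the empty subset's wells are drug-free controls
#' repeated at every step), giving `m * 2^d`. De-duplicating the identical
#' control wells and the zero level leaves `(m - 1) * (2^d - 1) + 1` unique
#' conditions. Both counts are returned.
#'
#' @param d Number of drugs (>= 1).
#' @param m Number of concentration levels per drug, counting zero
#'   (>= 2); the ladder then has `m - 1` nonzero steps.
#' @return A tibble with columns `d`, `m`, `formula_count`
#'   (`m * 2^d`) and `unique_condition_count`.
#' @examples
#' design_size(8, 10) # 2560 wells by the m * 2^d accounting
#' @export
design_size <- function(d, m) {
  stopifnot_scalar_number(d, "d")
  stopifnot_scalar_number(m, "m")
  if (d < 1 || d != round(d)) abort("`d` must be a positive integer.", class = "ndsynergy_invalid_parameter")
  if (m < 2 || m != round(m)) abort("`m` must be an integer >= 2.", class = "ndsynergy_invalid_parameter")
  tibble::tibble(
    d = as.integer(d),
    m = as.integer(m),
    formula_count = m * 2^d,
    unique_condition_count = (m - 1) * (2^d - 1) + 1
  )
}

#' Full-factorial (checkerboard) grid size
#'
#' Number of conditions `m^d` an exhaustive checkerboard of `d` drugs at
#' `m` levels each (zero included) would require.
#'
#' @inheritParams design_size
#' @return A number (`m^d`; may exceed integer range).
#' @examples
#' full_factorial_size(8, 10) # 1e8
#' @export
full_factorial_size <- function(d, m) {
  stopifnot_scalar_number(d, "d")
  stopifnot_scalar_number(m, "m")
  if (d < 1 || d != round(d)) abort("`d` must be a positive integer.", class = "ndsynergy_invalid_parameter")
  if (m < 2 || m != round(m)) abort("`m` must be an integer >= 2.", class = "ndsynergy_invalid_parameter")
  m^d
}

#' Dilution steps separating two concentrations
#'
#' How many `factor`-fold steps lie between concentrations `a` and `b`
#' (positive when `a > b`). Useful for relating a drug's breakpoint to its
#' MIC on the screen's gradient.
#'
#' @param a,b Concentrations (> 0), any common unit.
#' @param factor Fold change per step (> 1), default 2.
#' @return `log(a / b) / log(factor)`.
#' @examples
#' steps_between(0.25, 0.015625) # ciprofloxacin breakpoint vs MIC: 4 steps
#' @export
steps_between <- function(a, b, factor = 2) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0)) {
    abort("`a` and `b` must be finite and > 0.", class = "ndsynergy_invalid_parameter")
  }
  stopifnot_scalar_number(factor, "factor")
  if (factor <= 1) abort("`factor` must be > 1.", class = "ndsynergy_invalid_parameter")
  log(a / b) / log(factor)
}

#' Enumerate a normalized diagonal sampling design
#'
#' Generates the NDS design for a panel: every nonempty drug subset is
#' tested at every ladder ratio, with all drugs in the subset at the same
#' normalized concentration `ratio * N_i` (the subset's "diagonal"), plus
#' one drug-free control condition per replicate.
#'
#' @param panel A [drug_panel()].
#' @param ladder A [build_ladder()] result (or numeric vector of ratios).
#' @param replicates Replicate count per condition (>= 1).
#' @return A tibble of class `nds_design` with columns `plate`, `well`
#'   (`NA` until [randomize_layout()]), `replicate`, `subset`
#'   (semicolon-joined codes, `""` for controls), `step`, `ratio`, and one
#'   concentration column per drug (ug/mL), named by its code. Panel and
#'   ladder are carried as attributes.
#' @examples
#' panel <- ecoli_panel("MIC")
#' design <- enumerate_nds(panel, build_ladder(1, 2, 10), replicates = 2)
#' nrow(design)
#' @export
enumerate_nds <- function(panel, ladder, replicates = 1) {
  if (!inherits(panel, "drug_panel")) abort("`panel` must be a drug_panel.", class = "ndsynergy_invalid_parameter")
  ratios <- ladder_ratios(ladder)
  if (length(ratios) < 1) abort("`ladder` must have at least one step.", class = "ndsynergy_invalid_parameter")
  if (!is.numeric(replicates) || replicates < 1 || replicates != round(replicates)) {
    abort("`replicates` must be an integer >= 1.", class = "ndsynergy_invalid_parameter")
  }

  keys <- all_subset_keys(panel)
  grid <- tidyr::expand_grid(
    replicate = seq_len(replicates),
    subset = keys,
    step = seq_along(ratios)
  )
  grid$ratio <- ratios[grid$step]

  conc <- matrix(0, nrow = nrow(grid), ncol = nrow(panel),
                 dimnames = list(NULL, panel$asm_code))
  for (i in seq_len(nrow(panel))) {
    code <- panel$asm_code[i]
    present <- vapply(grid$subset, function(k) code %in% parse_subset(k), logical(1))
    conc[present, code] <- grid$ratio[present] * panel$normalization[i]
  }

  controls <- tibble::tibble(
    replicate = seq_len(replicates),
    subset = "",
    step = NA_integer_,
    ratio = NA_real_
  )
  zeros <- matrix(0, nrow = replicates, ncol = nrow(panel),
                  dimnames = list(NULL, panel$asm_code))

  out <- dplyr::bind_rows(
    dplyr::bind_cols(grid, tibble::as_tibble(conc)),
    dplyr::bind_cols(controls, tibble::as_tibble(zeros))
  )
  out <- dplyr::bind_cols(
    tibble::tibble(plate = NA_character_, well = NA_character_),
    out
  )
  structure(out,
            class = c("nds_design", class(out)),
            panel = panel,
            ladder = tibble::as_tibble(ladder_to_tibble(ladder)),
            replicates = as.integer(replicates))
}

ladder_to_tibble <- function(ladder) {
  if (is.data.frame(ladder)) ladder else tibble::tibble(step = seq_along(ladder), ratio = as.numeric(ladder))
}

design_panel <- function(design) attr(design, "panel")

#' Randomize a design onto plates
#'
#' Assigns each design point a `(plate, well)` position by a uniformly
#' random permutation, filling plates row-major after shuffling. The same
#' seed always yields the same layout. Randomizing positions guards the
#' screen against plate-position and edge effects.
#'
#' @param design An [enumerate_nds()] design.
#' @param wells_per_plate Plate capacity (default 96, labelled A1..H12;
#'   384 uses a 16 x 24 grid; other capacities get generic labels).
#' @param seed Integer seed for the permutation.
#' @return The design with `plate` and `well` filled in; no well is used
#'   twice.
#' @examples
#' design <- enumerate_nds(ecoli_panel(), build_ladder(1, 2, 3))
#' randomize_layout(design, seed = 7)
#' @export
randomize_layout <- function(design, wells_per_plate = 96, seed = 1) {
  if (!is.numeric(wells_per_plate) || wells_per_plate < 1) {
    abort("`wells_per_plate` must be >= 1.", class = "ndsynergy_invalid_parameter")
  }
  n <- nrow(design)
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  slot <- integer(n)
  slot[perm] <- seq_len(n) # design row perm[k] occupies slot k
  plate_no <- (slot - 1) %/% wells_per_plate + 1
  well_no <- (slot - 1) %% wells_per_plate + 1
  design$plate <- sprintf("P%02d", plate_no)
  design$well <- well_labels(wells_per_plate)[well_no]
  attr(design, "seed") <- as.integer(seed)
  design
}

well_labels <- function(wells_per_plate) {
  dims <- switch(as.character(wells_per_plate),
    "96" = c(8, 12),
    "384" = c(16, 24),
    NULL
  )
  if (is.null(dims)) {
    sprintf("W%03d", seq_len(wells_per_plate))
  } else {
    as.vector(t(outer(LETTERS[seq_len(dims[1])], seq_len(dims[2]), paste0)))
  }
}
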