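#' Minimax concentration of a condition
#'
#' The minimax concentration (MEC) of a concentration vector is the
#' largest normalized concentration among the drugs present: the "worst"
#' single-agent dose in the combination, on the panel's common scale.
#'
#' @param x Named numeric vector of concentrations (ug/mL), names being
#'   panel drug codes; zeros mean the drug is absent.
#' @param panel A [drug_panel()].
#' @return `max(x_i / N_i)` over the drugs with `x_i > 0`.
#' @examples
#' panel <- ecoli_panel("breakpoint")
#' mec(c(AMP = 8, ATM = 0.25), panel)
#' @export
mec <- function(x, panel) {
  x <- x[names(x) %in% panel$asm_code]
  if (all(x <= 0) || length(x) == 0) {
    abort("`x` must have at least one positive concentration.",
          class = "ndsynergy_invalid_input")
  }
  n_i <- panel$normalization[match(names(x), panel$asm_code)]
  max((x / n_i)[x > 0])
}

#' Reference combination-effect expectations
#'
#' Null-model expected effects for a combination given the individual
#' fractional growth reductions: Bliss independence multiplies survival
#' probabilities (`1 - prod(1 - e_i)`); Highest Single Agent takes the
#' best individual effect (`max(e_i)`).
#'
#' @param effects Numeric vector of individual fractional reductions in
#'   `[0, 1]`.
#' @return The expected combined fractional reduction.
#' @examples
#' bliss_expected(c(0.5, 0.8)) # 0.9
#' hsa_expected(c(0.5, 0.8)) # 0.8
#' @export
bliss_expected <- function(effects) {
  check_effects(effects)
  1 - prod(1 - effects)
}

#' @rdname bliss_expected
#' @export
hsa_expected <- function(effects) {
  check_effects(effects)
  max(effects)
}

check_effects <- function(effects) {
  if (length(effects) < 1 || any(!is.finite(effects)) ||
      any(effects < 0) || any(effects > 1)) {
    abort("`effects` must all lie in [0, 1].", class = "ndsynergy_invalid_parameter")
  }
  invisible(effects)
}

#' Interpret an Emergent Synergy Score
#'
#' ESS at or below 0.25 (a four-fold reduction over the best subset) is
#' called synergy; between 0.25 and 1, weak synergy; 1 or above, none.
#'
#' @param ess_value Numeric vector of ESS values.
#' @return Character vector: `"synergy"`, `"weak synergy"`, or `"none"`
#'   (`NA` in, `NA` out).
#' @examples
#' classify_ess(c(0.25, 0.5, 1))
#' @export
classify_ess <- function(ess_value) {
  dplyr::case_when(
    is.na(ess_value) ~ NA_character_,
    ess_value <= 0.25 ~ "synergy",
    ess_value < 1 ~ "weak synergy",
    TRUE ~ "none"
  )
}

# ---- internal scoring engine ------------------------------------------------

# Bitmask for a subset key given panel drug order.
subset_mask <- function(keys, panel) {
  codes <- panel$asm_code
  vapply(keys, function(k) {
    s <- parse_subset(k)
    sum(bitwShiftL(1L, match(s, codes) - 1L))
  }, integer(1), USE.NAMES = FALSE)
}

mask_to_key <- function(mask, panel) {
  codes <- panel$asm_code
  vapply(mask, function(m) {
    paste(codes[bitwAnd(m, bitwShiftL(1L, seq_along(codes) - 1L)) > 0L],
          collapse = ";")
  }, character(1))
}

# Per-row geometry of an effectiveness table: support mask, MEC (from
# concentrations and panel normalization), diagonal check, FIC sum.
eff_geometry <- function(eff, panel, rel_tol = 1e-9) {
  conc <- as.matrix(tibble::as_tibble(eff)[, panel$asm_code, drop = FALSE])
  ratio <- sweep(conc, 2, panel$normalization, "/")
  pos <- conc > 0
  mec <- apply(ifelse(pos, ratio, -Inf), 1, max)
  minr <- apply(ifelse(pos, ratio, Inf), 1, min)
  n_pos <- rowSums(pos)
  diagonal <- n_pos > 0 & (mec - pmin(minr, mec)) <= rel_tol * pmax(mec, 0)
  mask <- as.integer(pos %*% bitwShiftL(1L, seq_len(nrow(panel)) - 1L))
  fic <- as.numeric(sweep(conc, 2, panel$mic, "/") %*% rep(1, nrow(panel)))
  list(mask = mask, mec = mec, diagonal = diagonal, n_pos = n_pos, fic = fic)
}

# Smallest effective diagonal ratio per tested subset.
# closure = "monotone": smallest c_j such that every tested c >= c_j is
# effective (robust to an isolated effective call below an ineffective
# one, which under non-paradoxical growth must be noise); "raw": smallest
# effective c_j. Returns per-subset list with value (Inf = none effective)
# and whether the pattern was non-monotone.
diagonal_minima <- function(mec, effective, mask, closure) {
  out <- list()
  for (m in unique(mask)) {
    rows <- which(mask == m)
    ord <- rows[order(mec[rows], decreasing = TRUE)]
    eff_flags <- effective[ord]
    ratios <- mec[ord]
    nonmono <- any(diff(as.integer(eff_flags)) > 0) # effective below ineffective
    val <- if (closure == "monotone") {
      run <- cumprod(as.integer(eff_flags)) # 1 while top-down all effective
      if (run[1] == 0) Inf else min(ratios[run == 1])
    } else {
      if (any(eff_flags)) min(ratios[eff_flags]) else Inf
    }
    out[[as.character(m)]] <- list(value = val, nonmonotone = nonmono)
  }
  out
}

# Full MECI map over all nonempty submasks of `top_mask`, by the
# subset-inclusion recursion MECI(S) = min(diag_min(S), min_i MECI(S \ i)).
meci_map_engine <- function(eff, panel, closure, top_mask = NULL) {
  geom <- eff_geometry(eff, panel)
  drug_rows <- which(geom$n_pos > 0)
  if (any(!geom$diagonal[drug_rows])) {
    abort("Effectiveness table contains off-diagonal drug conditions; NDS scoring needs equal normalized concentrations within each subset.",
          class = "ndsynergy_invalid_input")
  }
  d <- nrow(panel)
  if (is.null(top_mask)) top_mask <- bitwShiftL(1L, d) - 1L

  dm <- diagonal_minima(geom$mec[drug_rows], eff$effective[drug_rows],
                        geom$mask[drug_rows], closure)

  submasks <- Filter(function(m) bitwAnd(m, top_mask) == m,
                     seq_len(bitwShiftL(1L, d) - 1L))
  missing <- submasks[!as.character(submasks) %in% names(dm)]
  if (length(missing)) {
    abort(paste0("Design incomplete: no diagonal conditions for subset(s) ",
                 paste(mask_to_key(missing, panel), collapse = ", ")),
          class = "ndsynergy_incomplete_design")
  }

  meci <- rep(Inf, bitwShiftL(1L, d) - 1L) # indexed by mask
  wit <- rep(NA_integer_, length(meci)) # witness subset mask
  nonmono <- character(0)
  for (m in submasks[order(vapply(submasks, bitcount, integer(1)))]) {
    entry <- dm[[as.character(m)]]
    if (entry$nonmonotone) nonmono <- c(nonmono, mask_to_key(m, panel))
    best <- entry$value
    best_wit <- m
    bits <- which(bitwAnd(m, bitwShiftL(1L, 0:(d - 1L))) > 0L)
    for (b in bits) {
      sub <- bitwAnd(m, bitwNot(bitwShiftL(1L, b - 1L)))
      if (sub > 0L && meci[sub] < best) {
        best <- meci[sub]
        best_wit <- wit[sub]
      }
    }
    meci[m] <- best
    wit[m] <- best_wit
  }
  if (length(nonmono)) {
    warn(paste0("Non-monotone effectiveness along the diagonal of subset(s) ",
                paste(unique(nonmono), collapse = ", "),
                "; possible paradoxical growth or replicate noise."))
  }
  list(meci = meci, witness = wit, submasks = submasks, geom = geom)
}

bitcount <- function(m) {
  n <- 0L
  while (m > 0L) {
    n <- n + bitwAnd(m, 1L)
    m <- bitwShiftR(m, 1L)
  }
  n
}

# ---- index operations -------------------------------------------------

#' MECI of a drug subset from NDS effectiveness data
#'
#' The Minimax Effective Concentration Index of a set of drugs is the
#' smallest minimax concentration over all effective tested conditions
#' whose support lies within the set. On NDS data this is the minimum,
#' over all nonempty subsets, of the smallest effective ratio on each
#' subset's diagonal.
#'
#' @param effectiveness An effectiveness table (see
#'   [quantify_effectiveness()]), or any tibble with `effective` plus
#'   per-drug concentration columns.
#' @param subset Character vector of drug codes (the target set), or a
#'   `";"`-joined key.
#' @param panel A [drug_panel()]; defaults to the panel attached to
#'   `effectiveness`.
#' @param closure `"monotone"` (default): the smallest ratio from which
#'   every tested higher ratio is also effective; `"raw"`: the smallest
#'   effective ratio regardless of calls above it.
#' @return A one-row tibble: `subset`, `meci` (`NA` when no tested
#'   condition of any subset is effective), `witness_subset`,
#'   `witness` (the achieving concentrations, `"CODE=conc"` joined by
#'   `";"`).
#' @examples
#' # see score_all_subsets() for an end-to-end example
#' @export
meci_from_nds <- function(effectiveness, subset, panel = NULL,
                          closure = c("monotone", "raw")) {
  closure <- match.arg(closure)
  panel <- panel %||% attr(effectiveness, "panel")
  if (is.null(panel)) abort("Supply `panel`.", class = "ndsynergy_invalid_parameter")
  key <- if (length(subset) == 1 && grepl(";", subset)) subset else subset_key(subset, panel)
  target <- subset_mask(key, panel)
  eng <- meci_map_engine(effectiveness, panel, closure, top_mask = target)
  meci_row(eng, target, panel)
}

meci_row <- function(eng, m, panel) {
  v <- eng$meci[m]
  w <- eng$witness[m]
  if (is.finite(v)) {
    wcodes <- parse_subset(mask_to_key(w, panel))
    conc <- v * panel$normalization[match(wcodes, panel$asm_code)]
    witness <- paste(sprintf("%s=%.10g", wcodes, conc), collapse = ";")
    tibble::tibble(subset = mask_to_key(m, panel), meci = v,
                   witness_subset = mask_to_key(w, panel), witness = witness)
  } else {
    tibble::tibble(subset = mask_to_key(m, panel), meci = NA_real_,
                   witness_subset = NA_character_, witness = NA_character_)
  }
}

#' Total and Emergent Synergy Scores from a MECI map
#'
#' `tss()` divides a combination's MECI by the best (smallest) MECI of
#' its single drugs; `ess()` divides by the best MECI over all proper
#' nonempty subsets. Values at most 1, with small values indicating that
#' the combination is effective at concentrations far below what any
#' single drug (TSS) or any sub-combination (ESS) requires.
#'
#' @param meci_map Named numeric vector of MECI values keyed by
#'   `";"`-joined subset codes; `NA` marks subsets with no effective
#'   tested condition (these are skipped in denominators).
#' @param subset Drug codes of the target combination (or a joined key).
#' @return The score, or `NA` when the required MECI values are missing
#'   or undefined.
#' @examples
#' m <- c(A = 1, B = 1, "A;B" = 0.25)
#' tss(m, c("A", "B"))
#' ess(m, c("A", "B"))
#' @export
tss <- function(meci_map, subset) {
  key <- as_key(subset)
  codes <- parse_subset(key)
  num <- meci_map[[key]]
  singles <- meci_map[names(meci_map) %in% codes]
  den <- suppressWarnings(min(singles, na.rm = TRUE))
  if (is.na(num) || !is.finite(den)) return(NA_real_)
  num / den
}

#' @rdname tss
#' @export
ess <- function(meci_map, subset) {
  key <- as_key(subset)
  codes <- parse_subset(key)
  if (length(codes) < 2) return(NA_real_)
  proper <- Filter(function(k) {
    s <- parse_subset(k)
    length(s) < length(codes) && all(s %in% codes)
  }, names(meci_map))
  num <- meci_map[[key]]
  den <- suppressWarnings(min(meci_map[proper], na.rm = TRUE))
  if (is.na(num) || !is.finite(den)) return(NA_real_)
  num / den
}

as_key <- function(subset) {
  if (length(subset) == 1) subset else paste(subset, collapse = ";")
}

#' Diagonal upper bound on the FICI
#'
#' The Fractional Inhibitory Concentration Index minimizes the summed
#' fraction-of-MIC over effective conditions. On NDS data only the
#' diagonals are sampled, so the minimum over sampled effective points is
#' an upper bound on the true FICI, never the exact value.
#'
#' @inheritParams meci_from_nds
#' @return The bound (`NA` when no sampled condition with support inside
#'   `subset` is effective).
#' @export
fici_diagonal_bound <- function(effectiveness, subset, panel = NULL) {
  panel <- panel %||% attr(effectiveness, "panel")
  if (is.null(panel)) abort("Supply `panel`.", class = "ndsynergy_invalid_parameter")
  key <- if (length(subset) == 1 && grepl(";", subset)) subset else subset_key(subset, panel)
  target <- subset_mask(key, panel)
  geom <- eff_geometry(effectiveness, panel)
  ok <- effectiveness$effective & geom$n_pos > 0 &
    bitwAnd(geom$mask, target) == geom$mask
  if (!any(ok)) return(NA_real_)
  min(geom$fic[ok])
}

#' Score every drug subset of a screen
#'
#' Computes, for each of the `2^d - 1` nonempty subsets of the panel:
#' the MECI (with witness condition), TSS, ESS, a diagonal FICI upper
#' bound, log2 scores, and the interpretive classification
#' (ESS <= 0.25 synergy; < 1 weak synergy; >= 1 none; no effective
#' condition found, indeterminate).
#'
#' @inheritParams meci_from_nds
#' @return A tibble of class `synergy_scores`, one row per nonempty
#'   subset, with the normalization label and closure rule attached.
#' @examples
#' panel <- drug_panel(c("a", "b"), c("A", "B"), mic = c(1, 1),
#'                     normalization = "MIC")
#' design <- enumerate_nds(panel, build_ladder(1, 2, 4))
#' eff <- tibble::tibble(design)[design$subset != "", ]
#' eff$effective <- (eff$subset == "A;B" & eff$ratio >= 0.25) | eff$ratio >= 1
#' score_all_subsets(eff, panel = panel)
#' @export
score_all_subsets <- function(effectiveness, panel = NULL,
                              closure = c("monotone", "raw")) {
  closure <- match.arg(closure)
  panel <- panel %||% attr(effectiveness, "panel")
  if (is.null(panel)) abort("Supply `panel`.", class = "ndsynergy_invalid_parameter")
  eng <- meci_map_engine(effectiveness, panel, closure)
  d <- nrow(panel)
  masks <- eng$submasks
  keys <- mask_to_key(masks, panel)
  sizes <- vapply(masks, bitcount, integer(1))
  meci <- ifelse(is.finite(eng$meci[masks]), eng$meci[masks], NA_real_)
  names(meci) <- keys

  single_mask <- bitwShiftL(1L, seq_len(d) - 1L)
  best_single <- vapply(masks, function(m) {
    s <- single_mask[bitwAnd(m, single_mask) > 0L]
    suppressWarnings(min(eng$meci[s]))
  }, numeric(1))
  best_proper <- vapply(masks, function(m) {
    if (bitcount(m) < 2) return(Inf)
    bits <- which(bitwAnd(m, single_mask) > 0L)
    suppressWarnings(min(vapply(bits, function(b) {
      eng$meci[bitwAnd(m, bitwNot(bitwShiftL(1L, b - 1L)))]
    }, numeric(1))))
  }, numeric(1))

  tss_v <- ifelse(is.na(meci) | !is.finite(best_single), NA_real_, meci / best_single)
  ess_v <- ifelse(is.na(meci) | !is.finite(best_proper), NA_real_, meci / best_proper)

  fici <- vapply(keys, function(k) fici_diagonal_bound(effectiveness, k, panel),
                 numeric(1))

  witness <- purrr::map_dfr(masks, meci_row, eng = eng, panel = panel)

  classification <- ifelse(is.na(meci), "indeterminate", classify_ess(ess_v))

  out <- tibble::tibble(
    subset = unname(keys),
    size = sizes,
    meci = unname(meci),
    log2_meci = log2_or_na(unname(meci)),
    tss = unname(tss_v),
    log2_tss = log2_or_na(unname(tss_v)),
    ess = unname(ess_v),
    log2_ess = log2_or_na(unname(ess_v)),
    fici_diagonal_bound = unname(fici),
    classification = unname(classification),
    witness = witness$witness,
    normalization_label = normalization_label(panel)
  )
  structure(out,
            class = c("synergy_scores", class(out)),
            panel = panel,
            closure = closure)
}

#' @export
tidy.synergy_scores <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize a scored screen
#'
#' One-row summary of a [score_all_subsets()] result for combinations of
#' two or more drugs: counts by classification (weak-synergy counting
#' follows the rule ESS < 1) and the lowest observed log2 ESS.
#'
#' @param x A `synergy_scores` tibble.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.synergy_scores <- function(x, ...) {
  multi <- x[x$size >= 2, ]
  tibble::tibble(
    n_subsets = nrow(x),
    n_combinations = nrow(multi),
    n_synergy = sum(multi$classification == "synergy", na.rm = TRUE),
    n_weak_synergy = sum(multi$classification == "weak synergy", na.rm = TRUE),
    n_indeterminate = sum(multi$classification == "indeterminate", na.rm = TRUE),
    min_log2_ess = suppressWarnings(min(multi$log2_ess, na.rm = TRUE)),
    normalization_label = x$normalization_label[1]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Histogram of log2 synergy scores
#'
#' Distribution of log2 TSS and log2 ESS across all scored combinations,
#' faceted by combination size; the standard at-a-glance view of a
#' screen (a spike at 0 means no synergy).
#'
#' @param object A `synergy_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synergy_scores <- function(object, ...) {
  df <- tibble::as_tibble(object) %>%
    dplyr::filter(.data$size >= 2) %>%
    tidyr::pivot_longer(dplyr::all_of(c("log2_tss", "log2_ess")),
                        names_to = "score", values_to = "log2_value") %>%
    dplyr::mutate(score = ifelse(.data$score == "log2_tss", "TSS", "ESS"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_value, fill = .data$score)) +
    ggplot2::geom_histogram(position = "dodge", binwidth = 0.5, na.rm = TRUE) +
    ggplot2::facet_wrap(~size, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "log2 score", y = "combinations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
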