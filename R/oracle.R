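# Brute-force verification machinery: exhaustive full-factorial MECI,
# paradoxical-growth ray checks, and empirical confirmation that diagonal
# sampling recovers the full-factorial MECI on non-paradoxical surfaces.

#' Full-factorial (checkerboard) MECI by exhaustive enumeration
#'
#' Solves the MECI minimization exactly over the complete checkerboard
#' grid built from the ladder levels (each drug at `ratio * N_i` or zero),
#' by enumerating every condition with support inside `subset` and
#' querying an effectiveness oracle. Makes no monotonicity assumption, so
#' it serves as an independent reference for the diagonal-sampling
#' estimate.
#'
#' @param effective A function taking a concentration matrix (one column
#'   per panel drug, ug/mL) and returning a logical vector of
#'   effectiveness calls.
#' @param panel A [drug_panel()].
#' @param ladder A [build_ladder()] result or numeric ratio vector.
#' @param subset Drug codes of the target set (or `";"`-joined key).
#' @return The exact grid MECI, or `NA` when no grid condition is
#'   effective.
#' @examples
#' panel <- drug_panel(c("a", "b"), c("A", "B"), mic = c(1, 1),
#'                     normalization = "MIC")
#' surf <- response_surface(panel, half_effect = c(0.5, 0.5))
#' full_factorial_meci(function(x) response(surf, x) <= 0.5,
#'                     panel, build_ladder(1, 2, 4), c("A", "B"))
#' @export
full_factorial_meci <- function(effective, panel, ladder, subset) {
  key <- if (length(subset) == 1 && grepl(";", subset)) subset else subset_key(subset, panel)
  codes <- parse_subset(key)
  ratios <- ladder_ratios(ladder)
  n_grid <- (length(ratios) + 1)^length(codes)
  if (n_grid > 1e6) {
    warn(sprintf("Enumerating %g grid points; this may be slow.", n_grid))
  }
  levels <- lapply(codes, function(code) {
    c(0, ratios * panel$normalization[match(code, panel$asm_code)])
  })
  names(levels) <- codes
  grid <- as.matrix(expand.grid(levels, KEEP.OUT.ATTRS = FALSE))
  conc <- matrix(0, nrow = nrow(grid), ncol = nrow(panel),
                 dimnames = list(NULL, panel$asm_code))
  conc[, codes] <- grid
  nonzero <- rowSums(conc > 0) > 0
  conc <- conc[nonzero, , drop = FALSE]
  ok <- effective(conc)
  if (!any(ok)) return(NA_real_)
  norm_ratio <- sweep(conc[ok, , drop = FALSE], 2, panel$normalization, "/")
  min(apply(norm_ratio, 1, max))
}

#' Check a dose-response ray for paradoxical growth
#'
#' Given responses measured along a ray (increasing amounts `c` of one
#' drug combination added to a fixed background), flags every scalar
#' triple `c1 < c2 < c3` where the response first drops
#' (`r(c2) < r(c1) - tol`) and then recovers (`r(c3) > r(c2) + tol`).
#' An empty violation list means the ray is consistent with
#' non-paradoxical growth at the given tolerance; a rise-then-fall
#' (hyperantagonism) is allowed and not flagged.
#'
#' @param c_scalars Strictly increasing ray scalars (>= 0).
#' @param responses Responses at each scalar.
#' @param tol Nonnegative tolerance; use the replicate noise scale for
#'   measured data, 0 for noiseless simulation.
#' @return A list of class `ray_check`: `violations` (tibble of index
#'   triples with their scalars and responses), `n_points`, `tol`, and
#'   logical `paradoxical`.
#' @examples
#' check_nonparadoxical(1:3, c(1.0, 0.8, 0.9))$paradoxical
#' @export
check_nonparadoxical <- function(c_scalars, responses, tol = 0) {
  n <- length(c_scalars)
  if (n != length(responses)) {
    abort("`c_scalars` and `responses` must have the same length.",
          class = "ndsynergy_invalid_input")
  }
  if (n < 3) abort("Need at least 3 points.", class = "ndsynergy_invalid_input")
  if (any(diff(c_scalars) <= 0)) {
    abort("`c_scalars` must be strictly increasing.", class = "ndsynergy_invalid_input")
  }
  if (tol < 0) abort("`tol` must be >= 0.", class = "ndsynergy_invalid_parameter")

  viol <- list()
  for (j in 2:(n - 1)) {
    before <- which(responses[1:(j - 1)] > responses[j] + tol)
    after <- which(responses[(j + 1):n] > responses[j] + tol)
    if (length(before) && length(after)) {
      i <- before[1]
      k <- j + after[1]
      viol[[length(viol) + 1]] <- tibble::tibble(
        i = i, j = j, k = k,
        c1 = c_scalars[i], c2 = c_scalars[j], c3 = c_scalars[k],
        r1 = responses[i], r2 = responses[j], r3 = responses[k]
      )
    }
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else {
    tibble::tibble(i = integer(), j = integer(), k = integer(),
                   c1 = numeric(), c2 = numeric(), c3 = numeric(),
                   r1 = numeric(), r2 = numeric(), r3 = numeric())
  }
  structure(list(violations = violations, n_points = n, tol = tol,
                 paradoxical = nrow(violations) > 0),
            class = "ray_check")
}

#' @export
print.ray_check <- function(x, ...) {
  cat(sprintf("<ray_check: %d points, tol=%g, %s (%d violating triple(s))>\n",
              x$n_points, x$tol,
              if (x$paradoxical) "PARADOXICAL" else "non-paradoxical",
              nrow(x$violations)))
  invisible(x)
}

#' Randomized ray checks on a response surface
#'
#' Draws random (background, direction) pairs in concentration space and
#' checks each resulting dose-response ray for paradoxical growth — the
#' in-silico analogue of probing random antibiotic ratios against fixed
#' background combinations.
#'
#' @param surface A [response_surface()].
#' @param n_rays Number of random rays.
#' @param seed Integer seed.
#' @param n_points Points per ray (scalars spread over `c_max`).
#' @param c_max Largest ray scalar.
#' @param tol Tolerance passed to [check_nonparadoxical()].
#' @return A tibble with one row per ray: `ray`, `n_violations`,
#'   `paradoxical`.
#' @export
sample_ray_checks <- function(surface, n_rays = 100, seed = 1, n_points = 50,
                              c_max = 2, tol = 0) {
  panel <- surface$panel
  d <- nrow(panel)
  cs <- seq(0, c_max, length.out = n_points)[-1] # strictly increasing, c > 0
  cs <- c(0, cs)
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(n_rays), function(ray) {
      x0 <- stats::runif(d, 0, 1) * surface$half_effect *
        stats::rbinom(d, 1, 0.5)
      dir <- stats::runif(d, 0, 1.5) * surface$half_effect *
        stats::rbinom(d, 1, 0.7)
      if (all(dir == 0)) dir <- surface$half_effect
      conc <- outer(cs, dir) + matrix(x0, length(cs), d, byrow = TRUE)
      colnames(conc) <- panel$asm_code
      chk <- check_nonparadoxical(cs, response(surface, conc), tol = tol)
      tibble::tibble(ray = ray, n_violations = nrow(chk$violations),
                     paradoxical = chk$paradoxical)
    })
  })
}

#' Empirically verify that diagonal sampling recovers the MECI
#'
#' For every nonempty drug subset, computes the MECI two independent
#' ways: from the diagonal design alone (noiseless effectiveness on the
#' NDS points, scored by [meci_from_nds()] semantics) and by exhaustive
#' enumeration of the full checkerboard grid built from the same ladder
#' levels ([full_factorial_meci()]). On a surface free of paradoxical
#' growth the two must agree exactly for every subset; on an
#' Eagle-effect surface they can disagree, which is exactly the failure
#' mode the non-paradoxical-growth assumption excludes.
#'
#' @param surface A [response_surface()].
#' @param ladder A [build_ladder()] result or ratio vector.
#' @param t Effectiveness threshold on the response scale.
#' @param closure Diagonal closure rule; `"raw"` (default) matches the
#'   minimization over sampled points exactly.
#' @return A tibble of class `theorem_report`: per subset, `meci_nds`,
#'   `meci_factorial`, `agree`. Use [glance()] for the agreement
#'   fraction.
#' @examples
#' panel <- drug_panel(c("a", "b"), c("A", "B"), mic = c(1, 1),
#'                     normalization = "MIC")
#' surf <- response_surface(panel, half_effect = c(0.5, 0.5))
#' verify_theorem(surf, build_ladder(1, 2, 5), t = 0.3)
#' @export
verify_theorem <- function(surface, ladder, t, closure = c("raw", "monotone")) {
  closure <- match.arg(closure)
  panel <- surface$panel
  design <- enumerate_nds(panel, ladder, replicates = 1)
  eff <- tibble::as_tibble(design)[design$subset != "", ]
  conc <- as_conc_matrix(eff, panel)
  eff$effective <- as.vector(ground_truth_effectiveness(surface, conc, t))

  eng <- meci_map_engine(eff, panel, closure)
  keys <- mask_to_key(eng$submasks, panel)
  nds <- ifelse(is.finite(eng$meci[eng$submasks]), eng$meci[eng$submasks],
                NA_real_)

  oracle_fn <- function(x) ground_truth_effectiveness(surface, x, t)
  factorial <- vapply(keys, function(k) {
    full_factorial_meci(oracle_fn, panel, ladder, k)
  }, numeric(1))

  agree <- (is.na(nds) & is.na(factorial)) |
    (!is.na(nds) & !is.na(factorial) &
       abs(nds - factorial) <= 1e-12 * pmax(1, abs(factorial)))

  out <- tibble::tibble(
    subset = keys,
    size = vapply(eng$submasks, bitcount, integer(1)),
    meci_nds = unname(nds),
    meci_factorial = unname(factorial),
    agree = unname(agree)
  )
  structure(out, class = c("theorem_report", class(out)),
            mode = surface$mode, threshold = t)
}

#' @export
glance.theorem_report <- function(x, ...) {
  tibble::tibble(
    n_subsets = nrow(x),
    n_agree = sum(x$agree),
    agreement = mean(x$agree),
    mode = attr(x, "mode")
  )
}

#' Draw a random non-paradoxical surface
#'
#' Randomized monotone-mode pooled-Hill surfaces for property checks:
#' half-effect doses scattered around the panel normalization, Hill and
#' pooling exponents across realistic ranges, and (with probability 1/2)
#' one random emergent-synergy interaction term.
#'
#' @param panel A [drug_panel()].
#' @param seed Integer seed.
#' @return A monotone-mode [response_surface()].
#' @export
random_monotone_surface <- function(panel, seed) {
  d <- nrow(panel)
  withr::with_seed(as.integer(seed), {
    half_effect <- panel$normalization * exp(stats::runif(d, -1.2, 0.4))
    hill <- stats::runif(1, 1.2, 4)
    pool <- stats::runif(1, 0.8, 6)
    interaction <- list()
    if (stats::runif(1) < 0.5 && d >= 2) {
      size <- sample(2:d, 1)
      s <- sort(sample(panel$asm_code, size))
      interaction[[paste(s, collapse = ";")]] <- stats::runif(1, 0.5, 6)
    }
    response_surface(panel, half_effect = half_effect, hill = hill,
                     pool_exponent = pool, interaction = interaction)
  })
}
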