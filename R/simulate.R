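#' Ground-truth dose-response surface
#'
#' A pooled-Hill family of multi-drug response surfaces used as simulation
#' ground truth. The effective dose of a condition `x` is
#' \deqn{E(x) = \left(\sum_i (x_i/D_i)^p\right)^{1/p} +
#'   \sum_S \beta_S \prod_{i \in S} x_i/D_i}
#' and the response declines with `E`:
#' * `"monotone"`: `r = r0 / (1 + E^h)` — nonincreasing along every ray
#'   from every background, i.e. free of paradoxical growth by
#'   construction.
#' * `"hyperantagonistic"`: `r = r0 (1 + a E) / (1 + E^h)` (`h > 1`) — a
#'   bounded rise before a monotone decline; still non-paradoxical.
#' * `"paradoxical"`: the monotone response times a recovery bump
#'   `1 + a exp(-((E - e0)/w)^2)` — an Eagle-effect-like dip-then-rise
#'   that violates the non-paradoxical-growth assumption.
#'
#' `p = 1` gives Loewe-like dose additivity, large `p` approaches
#' highest-single-agent pooling, and a positive interaction coefficient
#' `beta_S` injects an emergent synergy for subset `S` (the product term
#' only engages when every drug of `S` is present).
#'
#' @param panel A [drug_panel()].
#' @param half_effect Per-drug dose `D_i` (ug/mL) at which the drug alone
#'   gives `E = 1` (half-maximal response in monotone mode). Recycled.
#' @param hill Hill exponent `h` (> 0; > 1 for hyperantagonistic mode).
#' @param pool_exponent Pooling exponent `p` (> 0).
#' @param interaction Named list of interaction coefficients
#'   `beta_S >= 0`, keyed by `";"`-joined drug codes.
#' @param baseline Uninhibited response `r0` (> 0), in the units of the
#'   growth measure being emulated.
#' @param mode `"monotone"`, `"hyperantagonistic"` or `"paradoxical"`.
#' @param bump_height,bump_center,bump_width Eagle-mode recovery bump
#'   (`a`, `e0`, `w`); `bump_height` also sets `a` in hyperantagonistic
#'   mode.
#' @return An object of class `response_surface`.
#' @examples
#' panel <- drug_panel(c("a", "b"), c("A", "B"), mic = c(1, 2),
#'                     normalization = "MIC")
#' surf <- response_surface(panel, half_effect = c(1, 2))
#' response(surf, c(A = 1, B = 0))
#' @export
response_surface <- function(panel, half_effect, hill = 2, pool_exponent = 1,
                             interaction = list(), baseline = 1,
                             mode = c("monotone", "hyperantagonistic",
                                      "paradoxical"),
                             bump_height = 10, bump_center = 2,
                             bump_width = 0.4) {
  mode <- match.arg(mode)
  d <- nrow(panel)
  half_effect <- rep_len(as.numeric(half_effect), d)
  if (any(!is.finite(half_effect)) || any(half_effect <= 0)) {
    abort("`half_effect` doses must be finite and > 0.", class = "ndsynergy_invalid_parameter")
  }
  stopifnot_scalar_number(hill, "hill", positive = TRUE)
  stopifnot_scalar_number(pool_exponent, "pool_exponent", positive = TRUE)
  stopifnot_scalar_number(baseline, "baseline", positive = TRUE)
  if (mode == "hyperantagonistic" && hill <= 1) {
    abort("Hyperantagonistic mode needs `hill` > 1 for an eventual decline.",
          class = "ndsynergy_invalid_parameter")
  }
  if (length(interaction)) {
    if (is.null(names(interaction)) || any(!nzchar(names(interaction)))) {
      abort("`interaction` must be a named list keyed by drug subsets.",
            class = "ndsynergy_invalid_parameter")
    }
    bad <- vapply(interaction, function(b) !is.finite(b) || b < 0, logical(1))
    if (any(bad)) abort("Interaction coefficients must be >= 0.", class = "ndsynergy_invalid_parameter")
    names(interaction) <- vapply(names(interaction), function(k) {
      subset_key(parse_subset(k), panel)
    }, character(1))
  }
  structure(
    list(panel = panel, half_effect = half_effect, hill = hill,
         pool_exponent = pool_exponent, interaction = interaction,
         baseline = baseline, mode = mode,
         bump = list(height = bump_height, center = bump_center,
                     width = bump_width)),
    class = "response_surface"
  )
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface: %d drugs, mode=%s, h=%g, p=%g, r0=%g, %d interaction term(s)>\n",
              nrow(x$panel), x$mode, x$hill, x$pool_exponent, x$baseline,
              length(x$interaction)))
  invisible(x)
}

# Effective dose E(x); x is a matrix with one column per panel drug.
effective_dose <- function(surface, x) {
  z <- sweep(x, 2, surface$half_effect, "/")
  p <- surface$pool_exponent
  e <- rowSums(z^p)^(1 / p)
  for (k in names(surface$interaction)) {
    cols <- parse_subset(k)
    e <- e + surface$interaction[[k]] *
      apply(z[, cols, drop = FALSE], 1, prod)
  }
  e
}

#' Evaluate a response surface
#'
#' @param surface A [response_surface()].
#' @param x Named concentration vector (ug/mL), or a matrix / data frame
#'   with one column per panel drug.
#' @return Numeric response value(s); `x = 0` gives the baseline `r0`.
#' @export
response <- function(surface, x) {
  x <- as_conc_matrix(x, surface$panel)
  e <- effective_dose(surface, x)
  r0 <- surface$baseline
  h <- surface$hill
  base <- r0 / (1 + e^h)
  switch(surface$mode,
    monotone = base,
    hyperantagonistic = base * (1 + surface$bump$height * e),
    paradoxical = {
      b <- surface$bump
      base * (1 + b$height * exp(-((e - b$center) / b$width)^2))
    }
  )
}

as_conc_matrix <- function(x, panel) {
  codes <- panel$asm_code
  if (is.data.frame(x)) x <- as.matrix(x[, codes, drop = FALSE])
  if (is.matrix(x)) {
    x <- x[, codes, drop = FALSE]
  } else {
    full <- stats::setNames(numeric(length(codes)), codes)
    full[names(x)] <- x
    x <- matrix(full, nrow = 1, dimnames = list(NULL, codes))
  }
  if (any(x < 0)) abort("Concentrations must be >= 0.", class = "ndsynergy_invalid_parameter")
  x
}

#' Ground-truth effectiveness of a condition
#'
#' A condition is effective when its noiseless response is at or below
#' the threshold `t` (inclusive).
#'
#' @inheritParams response
#' @param t Response threshold.
#' @return Logical vector.
#' @export
ground_truth_effectiveness <- function(surface, x, t) {
  response(surface, x) <= t
}

#' Synthesize plate-reader readings for a design
#'
#' Generates a 24 h, 15-minute-cadence OD600 time series for every well
#' of a design: a logistic growth curve whose carrying capacity above
#' background scales with `r(x) / r0`, plus additive Gaussian noise. The
#' noiseless area under the curve is exactly proportional to the surface
#' response, so effectiveness thresholds transfer between response and
#' AUGC scales.
#'
#' @param surface A [response_surface()].
#' @param design A randomized [enumerate_nds()] design (or any tibble
#'   with `plate`, `well` and per-drug concentration columns).
#' @param noise_sd Gaussian OD noise standard deviation (default 0.01).
#' @param seed Integer seed; the same seed regenerates the identical
#'   dataset.
#' @param hours,cadence_min Measurement schedule (default 24 h every
#'   15 min).
#' @param background Media-blank OD600.
#' @param od_capacity Carrying capacity above background of an
#'   uninhibited well.
#' @param growth_rate Logistic steepness (1/hour).
#' @param midpoint_hours Logistic midpoint (hours).
#' @param threshold_frac Fraction of baseline used for the ground-truth
#'   effectiveness call stored in `truth` (default 0.1).
#' @return A list of class `simulated_dataset` with elements `readings`
#'   (long-format tibble), `truth` (per-well noiseless `response` and
#'   `effective`), `design`, and `seed`.
#' @export
synthesize_readings <- function(surface, design, noise_sd = 0.01, seed = 1,
                                hours = 24, cadence_min = 15,
                                background = 0.05, od_capacity = 1,
                                growth_rate = 0.8, midpoint_hours = 8,
                                threshold_frac = 0.1) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "ndsynergy_invalid_parameter")
  panel <- surface$panel
  design_tbl <- tibble::as_tibble(design)
  if (any(is.na(design_tbl$plate)) || any(is.na(design_tbl$well))) {
    abort("Design wells are unassigned; run randomize_layout() first.",
          class = "ndsynergy_invalid_parameter")
  }
  conc <- as_conc_matrix(design_tbl, panel)
  r <- response(surface, conc)
  rel <- r / surface$baseline

  t_min <- seq(0, hours * 60, by = cadence_min)
  shape <- stats::plogis(growth_rate * (t_min / 60 - midpoint_hours))

  n_wells <- nrow(design_tbl)
  n_t <- length(t_min)
  od <- background + od_capacity * outer(rel, shape)
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(n_wells * n_t, sd = noise_sd), n_wells, n_t)
    })
    od <- od + noise
  }

  readings <- tibble::tibble(
    plate = rep(design_tbl$plate, each = n_t),
    well = rep(design_tbl$well, each = n_t),
    time_min = rep(t_min, times = n_wells),
    od600 = as.vector(t(od))
  )
  truth <- dplyr::bind_cols(
    design_tbl[, c("plate", "well", "subset", "step", "ratio", panel$asm_code)],
    tibble::tibble(response = r,
                   effective = r <= threshold_frac * surface$baseline)
  )
  structure(list(readings = readings, truth = truth, design = design,
                 seed = as.integer(seed)),
            class = "simulated_dataset")
}

#' Read a response-surface configuration
#'
#' YAML with `half_effect` (ug/mL, named by drug code or in panel order),
#' `hill`, `pool_exponent`, `baseline`, `mode`, optional `interaction`
#' (map from `";"`-joined subsets to coefficients) and bump parameters.
#'
#' @param path File path.
#' @param panel The [drug_panel()] the surface is defined over.
#' @return A [response_surface()].
#' @export
read_surface <- function(path, panel) {
  cfg <- yaml::read_yaml(path)
  he <- unlist(cfg$half_effect)
  if (!is.null(names(he)) && all(nzchar(names(he)))) {
    he <- he[panel$asm_code]
  }
  response_surface(
    panel,
    half_effect = as.numeric(he),
    hill = cfg$hill %||% 2,
    pool_exponent = cfg$pool_exponent %||% 1,
    interaction = cfg$interaction %||% list(),
    baseline = cfg$baseline %||% 1,
    mode = cfg$mode %||% "monotone",
    bump_height = cfg$bump_height %||% 10,
    bump_center = cfg$bump_center %||% 2,
    bump_width = cfg$bump_width %||% 0.4
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset: %d wells x %d timepoints, seed %d>\n",
              nrow(x$truth), length(unique(x$readings$time_min)), x$seed))
  invisible(x)
}
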