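---
title: "Screening high-order antibiotic synergy with normalized diagonal sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening high-order antibiotic synergy with normalized diagonal sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndsynergy)
library(dplyr)
```

## The problem

Testing whether `d` antibiotics interact synergistically at `m`
concentration levels each is, done exhaustively, an `m^d` checkerboard:
eight drugs at ten concentrations would need 10^8 wells. `ndsynergy`
implements a screening framework that replaces the checkerboard with
**normalized diagonal sampling (NDS)**: every drug subset is tested only
at equal *normalized* concentrations of all its members, which costs
`m * 2^d` wells (2,560 for the eight-drug case) and — under one
biological assumption discussed below — loses nothing.

## The score: minimax effective concentration

Each drug `i` carries a normalization constant `N_i` (its MIC, its
EUCAST susceptible breakpoint, or a custom clinical dose). For a
condition `x` (a vector of concentrations), the *minimax concentration*
is `max_i x_i / N_i`, the highest single-agent dose on the common scale.
A condition is *effective* when a growth measure falls at or below a
threshold `t`. The **Minimax Effective Concentration Index** of a drug
set `S` is

    MECI(S) = min { max_i x_i / N_i : x effective, support(x) ⊆ S },

the cheapest effective condition in minimax terms. Two ratios interpret
it:

* **TSS** (total synergy) `= MECI(S) / min over singletons i in S of MECI({i})`,
* **ESS** (emergent synergy) `= MECI(S) / min over proper subsets S' of MECI(S')`.

Both are at most 1 and `TSS <= ESS` always, since the ESS denominator
minimizes over a superset of the TSS denominator's candidates. ESS at or
below 0.25 — a four-fold improvement over the best sub-combination — is
classified `"synergy"`; between 0.25 and 1, `"weak synergy"`. The 0.25
boundary is inclusive, chosen to coincide with the classical FICI cutoff
of 0.5 for a pair: a pair effective with both drugs at a quarter of their
MICs has summed fractional concentration 0.5 and ESS 0.25. On diagonal
data the package also reports the minimum summed fraction-of-MIC over
effective sampled points, always labelled a *FICI upper bound*: the exact
FICI minimizes over the full checkerboard, which the design deliberately
does not measure.

When no tested condition of any subset is effective the MECI is reported
as `NA` and the subset is classified `"indeterminate"`; such subsets are
skipped in ESS/TSS denominators as long as at least one subset remains
defined.

## Why the diagonal suffices

The correctness of NDS rests on *absence of paradoxical growth*: along
any ray in concentration space (adding increasing amounts of one drug
combination to any fixed background), once the response starts falling it
never rises again. Rising *before* falling (hyperantagonism) is allowed;
an Eagle-effect dip-then-rise is not. Under that assumption, the minimax
optimum for every subset is attained on that subset's diagonal, so the
design's `m * 2^d` wells identify every MECI exactly.

The package does not re-prove this; it verifies it empirically.
`verify_theorem()` computes every subset's MECI twice — from the diagonal
design alone and by brute-force enumeration of the full grid
(`full_factorial_meci()`) — and reports per-subset agreement.
`check_nonparadoxical()` tests sampled rays for violating triples, and
`sample_ray_checks()` automates that over random backgrounds and
directions. The test suite runs 20 random non-paradoxical surfaces at
each of `d` = 2, 3, 4 with a six-step two-fold ladder (grids up to
`7^4` = 2,401 points; small enough to enumerate in seconds, large enough
that all 15 subsets are exercised) and demands 100% agreement, plus over
100 random rays with zero violations. A constructed Eagle-effect surface
must conversely produce at least one disagreeing subset *and* a flagged
ray — the framework's own negative control.

## The simulator

No generative model is prescribed by the screening method itself, so the
package defines one with the properties the verification needs. A
surface maps a condition to an *effective dose*

    E(x) = (sum_i (x_i / D_i)^p)^(1/p) + sum_S beta_S prod_{i in S} x_i / D_i

and a response `r = r0 / (1 + E^h)`. This pooled-Hill family was chosen
because (a) in monotone mode `E` is nondecreasing in every coordinate, so
`r` is nonincreasing along every ray — non-paradoxical by construction,
not by test; (b) the pooling exponent `p` spans Loewe-like dose addition
(`p = 1`) through highest-single-agent-like pooling (large `p`); and
(c) a single coefficient `beta_S` injects an emergent synergy for exactly
the subset `S`, because the product term vanishes unless every member is
present. Hyperantagonistic mode multiplies by `1 + aE` (bounded rise,
then monotone decline — still legal), and paradoxical mode multiplies by
a Gaussian recovery bump `1 + a exp(-((E - e0)/w)^2)`, the minimal
mechanism producing an Eagle-effect dip.

`synthesize_readings()` turns a surface plus a design into plate-reader
data: a logistic OD600 curve over 24 h at 15-minute cadence whose
carrying capacity above background scales with `r(x)/r0`, plus additive
Gaussian noise (default sd 0.01 OD, a typical plate-reader repeatability
figure), duplicate wells, and fully randomized plate layout under a
single recorded seed. Because capacity scales linearly, the noiseless
area under the curve is exactly proportional to `r(x)`, so a threshold
of fraction `f` of the drug-free control AUGC corresponds to `r <= f r0`
on the response scale.

What the simulator does *not* emulate: lag-phase and carrying-capacity
variation between wells, plate edge and day effects, autocorrelated
reader drift, and any mechanistic pharmacodynamics. Passing tests
therefore show that the analysis pipeline is correct given data whose
growth summary is faithful to an underlying dose-response surface — they
do not show that any particular laboratory's noise structure is benign.
The randomized layout and replicate aggregation exist precisely for the
artifacts the simulator leaves out.

## Growth quantification choices

Effectiveness defaults to **AUGC**: the trapezoidal integral of
background-subtracted OD600 over the first 24 h (units OD·hours),
computed on actual timestamps with no resampling. Decisions where the
convention was genuinely open:

* *Background.* Default is the well's first in-window reading,
  overridable by a blank estimate. With real data the per-well read
  absorbs well-to-well offsets; with simulated data the known media
  blank is preferable, because subtracting a single noisy reading
  propagates its error across the whole 24 h integral (±0.01 OD at the
  first read shifts AUGC by ±0.24 OD·h).
* *Negative values.* `od - background` is not clamped at zero for AUGC;
  noise dips below background, and clamping would bias areas upward.
* *Threshold.* "Complete inhibition" is operationalized as AUGC at most
  a fraction `f` of the mean drug-free control AUGC, default `f = 0.1`;
  absolute thresholds are also accepted. The comparison is inclusive.
* *Replicates.* Default rule averages replicate measures before
  thresholding (`"all"` and `"any"` are available).
* *Growth rate.* The alternative measure — maximum slope of a centered
  five-point moving average of log(OD - background), natural log, per
  hour, windows truncated at the series ends, non-positive values
  excluded — is implemented and reported but not used for effectiveness
  by default, mirroring its role as a concordant secondary measure.

On real diagonals, noise can make effectiveness non-monotone in
concentration. The default `"monotone"` closure takes the smallest ratio
from which *every* higher tested ratio is effective and warns about the
non-monotone pattern (a potential assumption violation worth inspecting);
`"raw"` takes the smallest effective ratio as measured. On noiseless data
the two coincide; `verify_theorem()` uses `"raw"` so that the diagonal
estimate is exactly the minimization over sampled points.

## Design accounting

Two well counts are reported by `design_size()`. The `m * 2^d` formula
counts the empty subset's (identical) control wells at every level; the
de-duplicated count `(m - 1)(2^d - 1) + 1` is what `enumerate_nds()`
actually generates per replicate, treating the ladder as `m - 1` nonzero
steps with zero as the m-th level. For eight drugs and `m = 10` these are
2,560 and 2,296; at 96 wells per plate the de-duplicated duplicate
screen fits on 27 plates by plain ceiling arithmetic. Concentrations are
serialized as decimal text at full round-trip precision, so a written
design re-reads bit-identically.

## A worked run

```{r worked}
panel <- drug_panel(
  name = c("drug-a", "drug-b"), asm_code = c("A", "B"),
  mic = c(16, 0.25), normalization = "MIC"
)
surface <- response_surface(
  panel, half_effect = panel$normalization / 3.2, hill = 2,
  pool_exponent = 8, interaction = list("A;B" = 4.5)
)
design <- randomize_layout(
  enumerate_nds(panel, build_ladder(1, 2, 6), replicates = 2),
  seed = 7
)
sim <- synthesize_readings(surface, design, noise_sd = 0.01, seed = 8)
eff <- quantify_effectiveness(sim$readings, design, threshold_frac = 0.1,
                              background = 0.05)
scores <- score_all_subsets(eff)
tidy(scores)
glance(scores)
```

The pair is recovered as `"synergy"` with ESS 0.25 (both drugs effective
together at a quarter of the MIC each single one needs), and the
diagonal FICI bound of 0.5 sits exactly at the classical cutoff.

```{r plot, fig.width = 6, fig.height = 3}
autoplot(scores)
```

## Verifying the design on the simulator

```{r verify}
report <- verify_theorem(surface, build_ladder(1, 2, 6), t = 0.1)
report
glance(report)$agreement
```

```{r eagle}
eagle <- response_surface(panel, half_effect = c(16, 0.25), hill = 4,
                          pool_exponent = 1, mode = "paradoxical",
                          bump_height = 20, bump_center = 2.5,
                          bump_width = 0.5)
glance(verify_theorem(eagle, build_ladder(1, 2, 6), t = 0.3))$agreement
```

## Limitations

* The guarantees concern synergy only: the asymmetry of the
  non-paradoxical-growth assumption means an analogous antagonism index
  would not be identified by diagonal sampling, and none is provided.
* The diagonal FICI value is an upper bound; no Loewe isobole analysis
  beyond it is attempted.
* Scores are only as meaningful as the normalization: a combination can
  be synergistic relative to breakpoints but not MICs (or vice versa),
  which is why every output row carries the normalization label.
* Exhaustive verification is bounded by grid growth (`(steps + 1)^d`);
  the defaults keep it to five drugs or fewer, with randomized spot
  checks the practical tool beyond that.
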