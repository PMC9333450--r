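# Shared fixtures, all built in code.

# Plain data.frame with only core attributes, for content comparisons.
strip_attrs <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "row.names", "class")]
  x
}

two_drug_mic_panel <- function(mic = c(1, 2)) {
  drug_panel(c("drug-a", "drug-b"), c("A", "B"), mic = mic,
             normalization = "MIC")
}

generic_panel <- function(d, mic = NULL) {
  mic <- mic %||% rep(1, d)
  drug_panel(paste0("drug-", letters[1:d]), LETTERS[1:d], mic = mic,
             normalization = "MIC")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effectiveness table where each single drug is effective from ratio 1 and
# one chosen subset's diagonal is effective from `ratio_on`; all other
# multi-drug diagonals effective from ratio 1.
toy_effectiveness <- function(panel, steps = 4, synergy_subset = NULL,
                              ratio_on = 0.25) {
  design <- enumerate_nds(panel, build_ladder(1, 2, steps))
  eff <- tibble::as_tibble(design)[design$subset != "", ]
  eff$effective <- eff$ratio >= 1
  if (!is.null(synergy_subset)) {
    hit <- eff$subset == synergy_subset
    eff$effective[hit] <- eff$ratio[hit] >= ratio_on
  }
  eff
}

# The end-to-end simulation scenario: d = 4, every single drug effective at
# its MIC, one pair carrying an emergent interaction that makes its diagonal
# effective at a quarter of the single-drug ratio.
injected_synergy_scenario <- function(seed = 11) {
  panel <- drug_panel(paste0("drug", 1:4), c("A", "B", "C", "D"),
                      mic = c(16, 0.25, 8, 0.5), normalization = "MIC")
  # with hill 2 and a 10%-of-control threshold the single-drug effective
  # dose is 3 * D_i; D_i = MIC_i / 3.2 puts each single's onset at its MIC
  # with a noise margin on the effective side
  surface <- response_surface(panel, half_effect = panel$normalization / 3.2,
                              hill = 2, pool_exponent = 8,
                              interaction = list("A;B" = 4.5))
  ladder <- build_ladder(1, 2, 8)
  design <- randomize_layout(enumerate_nds(panel, ladder, replicates = 2),
                             seed = seed)
  list(panel = panel, surface = surface, ladder = ladder, design = design,
       synergy_subset = "A;B")
}

# Eagle-effect surface whose effective region is an off-diagonal island the
# diagonal design cannot see (dip in the response along rising dose).
eagle_surface <- function() {
  panel <- generic_panel(2)
  response_surface(panel, half_effect = c(1, 1), hill = 4, pool_exponent = 1,
                   mode = "paradoxical", bump_height = 20, bump_center = 2.5,
                   bump_width = 0.5)
}
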