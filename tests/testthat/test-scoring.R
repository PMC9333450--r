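test_that("minimax concentration is the largest normalized dose present", {
  panel <- ecoli_panel("breakpoint")
  expect_equal(mec(c(AMP = 8, ATM = 0.25), panel), 1)
  expect_equal(mec(c(CIP = 0.25), panel), 1) # single drug at its N_i
  p <- two_drug_mic_panel(mic = c(4, 8))
  expect_equal(mec(c(A = 1, B = 2), p), 0.25) # both at a quarter MIC
  expect_error(mec(c(A = 0, B = 0), p), class = "ndsynergy_invalid_input")
})

test_that("Bliss and HSA expectations match their null models", {
  expect_equal(bliss_expected(c(0.5, 0.8)), 0.9)
  expect_equal(hsa_expected(c(0.5, 0.8)), 0.8)
  expect_equal(bliss_expected(0.37), 0.37)
  expect_equal(bliss_expected(c(0.2, 1, 0.6)), 1)
  expect_error(bliss_expected(c(0.5, 1.2)), class = "ndsynergy_invalid_parameter")
  # Bliss dominates HSA everywhere on [0,1]^k
  withr::with_seed(1, {
    for (i in 1:50) {
      e <- runif(sample(2:5, 1))
      expect_gte(bliss_expected(e), hsa_expected(e))
    }
  })
})

test_that("ESS classification uses the inclusive 0.25 boundary", {
  expect_equal(classify_ess(c(0.25, 0.5, 1, 1.4, NA)),
               c("synergy", "weak synergy", "none", "none", NA))
})

test_that("MECI from NDS data takes the minimum over all subset diagonals", {
  p <- two_drug_mic_panel(mic = c(1, 1))
  # singleton effective exactly at its MIC -> MECI 1
  eff <- toy_effectiveness(p, steps = 4)
  one <- meci_from_nds(eff, "A", panel = p)
  expect_equal(one$meci, 1)
  # pair diagonal effective down to 0.25 -> MECI 0.25 with a pair witness
  eff_syn <- toy_effectiveness(p, steps = 4, synergy_subset = "A;B")
  pair <- meci_from_nds(eff_syn, c("A", "B"), panel = p)
  expect_equal(pair$meci, 0.25)
  expect_equal(pair$witness_subset, "A;B")
  # nothing effective anywhere -> NA sentinel
  eff_none <- eff
  eff_none$effective <- FALSE
  none <- meci_from_nds(eff_none, c("A", "B"), panel = p)
  expect_true(is.na(none$meci))
  # incomplete design: a missing diagonal is a hard error naming the subset
  expect_error(meci_from_nds(eff[eff$subset != "B", ], c("A", "B"), panel = p),
               class = "ndsynergy_incomplete_design")
})

test_that("monotone closure ignores isolated effective calls below a gap", {
  p <- two_drug_mic_panel(mic = c(1, 1))
  eff <- toy_effectiveness(p, steps = 5)
  # plant a non-monotone pattern on A's diagonal: effective at 1 and 0.25 only
  idx <- eff$subset == "A" & eff$ratio == 0.25
  eff$effective[idx] <- TRUE
  expect_warning(
    mono <- meci_from_nds(eff, "A", panel = p, closure = "monotone"),
    "Non-monotone"
  )
  expect_equal(mono$meci, 1)
  expect_warning(
    raw <- meci_from_nds(eff, "A", panel = p, closure = "raw"),
    "Non-monotone"
  )
  expect_equal(raw$meci, 0.25)
})

test_that("TSS and ESS follow their ratio definitions", {
  m <- c(A = 1, B = 1, "A;B" = 0.25)
  expect_equal(tss(m, c("A", "B")), 0.25)
  expect_equal(ess(m, c("A", "B")), 0.25)
  # MIC normalization with singles at MIC: TSS equals the MECI
  expect_equal(tss(m, c("A", "B")), m[["A;B"]] / 1)
  # no improvement over the best single
  m2 <- c(A = 0.25, B = 1, "A;B" = 0.5)
  expect_equal(tss(m2, c("A", "B")), 2)
  expect_equal(classify_ess(ess(m2, c("A", "B"))), "none")
  # triple whose best pair already achieves the same MECI: ESS 1, TSS < 1
  m3 <- c(A = 1, B = 1, C = 1, "A;B" = 0.25, "A;C" = 1, "B;C" = 1,
          "A;B;C" = 0.25)
  expect_equal(ess(m3, c("A", "B", "C")), 1)
  expect_equal(tss(m3, c("A", "B", "C")), 0.25)
  # NA (not-found) subsets are skipped in denominators
  m4 <- c(A = NA, B = 1, "A;B" = 0.5)
  expect_equal(ess(m4, c("A", "B")), 0.5)
  expect_true(is.na(ess(c(A = NA, B = NA, "A;B" = 0.5), c("A", "B"))))
})

test_that("diagonal FICI bound minimizes the summed fraction of MIC", {
  p <- two_drug_mic_panel(mic = c(1, 1))
  eff <- toy_effectiveness(p, steps = 4, synergy_subset = "A;B")
  # pair effective at quarter MIC each: bound 0.25 + 0.25 = 0.5
  expect_equal(fici_diagonal_bound(eff, c("A", "B"), panel = p), 0.5)
  # single drug effective at MIC: bound 1
  expect_equal(fici_diagonal_bound(eff, "A", panel = p), 1)
  # off-diagonal supplied point: quarter + half MIC -> FIC 0.75
  extra <- eff[1, ]
  extra$A <- 0.25
  extra$B <- 0.5
  extra$effective <- TRUE
  singles_only <- eff[eff$subset %in% c("A", "B"), ]
  expect_equal(fici_diagonal_bound(rbind(singles_only, extra),
                                   c("A", "B"), panel = p), 0.75)
  none <- eff
  none$effective <- FALSE
  expect_true(is.na(fici_diagonal_bound(none, c("A", "B"), panel = p)))
})

test_that("scoring every subset yields consistent scores and classifications", {
  p <- generic_panel(3)
  eff <- toy_effectiveness(p, steps = 4, synergy_subset = "A;B")
  sc <- score_all_subsets(eff, panel = p)
  expect_equal(nrow(sc), 7)
  expect_equal(sc$meci[sc$subset == "A;B"], 0.25)
  expect_equal(sc$ess[sc$subset == "A;B"], 0.25)
  expect_equal(sc$classification[sc$subset == "A;B"], "synergy")
  # the superset inherits the pair's MECI, so its emergent score is 1
  expect_equal(sc$meci[sc$subset == "A;B;C"], 0.25)
  expect_equal(sc$ess[sc$subset == "A;B;C"], 1)
  expect_equal(sc$tss[sc$subset == "A;B;C"], 0.25)
  expect_equal(sc$normalization_label, rep("MIC", 7))

  # d = 8 panel: 255 rows, 247 of size >= 2
  p8 <- generic_panel(8)
  eff8 <- toy_effectiveness(p8, steps = 2)
  sc8 <- score_all_subsets(eff8, panel = p8)
  expect_equal(nrow(sc8), 255)
  expect_equal(sum(sc8$size >= 2), 247)

  # all-inert screen: everything indeterminate
  inert <- eff
  inert$effective <- FALSE
  sc_inert <- score_all_subsets(inert, panel = p)
  expect_true(all(sc_inert$classification == "indeterminate"))
  expect_true(all(is.na(sc_inert$meci)))

  # glance counts weak synergy with the ESS < 1 rule
  g <- glance(sc)
  expect_equal(g$n_synergy, 1)
  expect_equal(g$min_log2_ess, -2)
})

test_that("score invariants hold across random effectiveness patterns", {
  for (seed in 1:10) {
    p <- generic_panel(3)
    des <- enumerate_nds(p, build_ladder(1, 2, 5))
    eff <- tibble::as_tibble(des)[des$subset != "", ]
    withr::with_seed(seed, {
      # upward-closed random pattern per diagonal (random onset step)
      onsets <- stats::setNames(sample(0:6, 7, replace = TRUE),
                                unique(eff$subset))
      eff$effective <- eff$step <= onsets[eff$subset]
    })
    sc <- score_all_subsets(eff, panel = p)
    ok <- !is.na(sc$tss) & !is.na(sc$ess)
    expect_true(all(sc$tss[ok] <= sc$ess[ok] + 1e-12))
    expect_true(all(sc$ess[ok] <= 1 + 1e-12))
    # MECI nonincreasing under subset inclusion
    meci <- stats::setNames(sc$meci, sc$subset)
    for (key in sc$subset[sc$size >= 2]) {
      codes <- strsplit(key, ";")[[1]]
      subs <- sc$subset[vapply(sc$subset, function(k) {
        s <- strsplit(k, ";")[[1]]
        length(s) < length(codes) && all(s %in% codes)
      }, logical(1))]
      if (!is.na(meci[key])) {
        expect_true(all(meci[key] <= meci[subs] + 1e-12, na.rm = TRUE))
      }
    }
  }
})

test_that("rescaling every normalization by a common factor cancels in TSS/ESS", {
  p <- drug_panel(c("a", "b", "c"), c("A", "B", "C"), mic = c(2, 4, 8),
                  normalization = "MIC")
  eff <- toy_effectiveness(p, steps = 4, synergy_subset = "B;C",
                           ratio_on = 0.5)
  sc <- score_all_subsets(eff, panel = p)
  lambda <- 4
  p_scaled <- drug_panel(c("a", "b", "c"), c("A", "B", "C"),
                         mic = c(2, 4, 8), normalization = "custom",
                         custom = lambda * c(2, 4, 8))
  sc2 <- score_all_subsets(eff, panel = p_scaled)
  expect_equal(sc2$meci, sc$meci / lambda)
  expect_equal(sc2$tss, sc$tss)
  expect_equal(sc2$ess, sc$ess)
  expect_equal(sc2$classification, sc$classification)
})

test_that("scores are invariant to drug order in the panel", {
  p <- drug_panel(c("a", "b", "c"), c("A", "B", "C"), mic = c(2, 4, 8),
                  normalization = "MIC")
  eff <- toy_effectiveness(p, steps = 4, synergy_subset = "A;C",
                           ratio_on = 0.25)
  sc <- score_all_subsets(eff, panel = p)
  perm <- c(3, 1, 2)
  p_perm <- drug_panel(c("a", "b", "c")[perm], c("A", "B", "C")[perm],
                       mic = c(2, 4, 8)[perm], normalization = "MIC")
  sc_perm <- score_all_subsets(eff, panel = p_perm)
  canon <- function(s) paste(sort(strsplit(s, ";")[[1]]), collapse = ";")
  a <- strip_attrs(sc)[, c("subset", "meci", "tss", "ess")]
  b <- strip_attrs(sc_perm)[, c("subset", "meci", "tss", "ess")]
  a$subset <- unname(vapply(a$subset, canon, character(1)))
  b$subset <- unname(vapply(b$subset, canon, character(1)))
  expect_equal(dplyr::arrange(a, subset), dplyr::arrange(b, subset))
})

test_that("tidy and autoplot work on score tables", {
  p <- generic_panel(3)
  sc <- score_all_subsets(toy_effectiveness(p, steps = 3), panel = p)
  expect_s3_class(tidy(sc), "tbl_df")
  plt <- autoplot(sc)
  expect_s3_class(plt, "ggplot")
})
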