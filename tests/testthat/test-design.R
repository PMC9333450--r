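test_that("dilution ladders follow the geometric formula", {
  expect_equal(build_ladder(1, 2, 3)$ratio, c(1, 0.5, 0.25))
  lad10 <- build_ladder(1, 2, 10)
  expect_length(lad10$ratio, 10)
  expect_equal(lad10$ratio[10], 2^-9)
  expect_equal(build_ladder(1, 2, 1)$ratio, 1)
  expect_true(all(diff(lad10$ratio) < 0))

  expect_error(build_ladder(0, 2, 3), class = "ndsynergy_invalid_parameter")
  expect_error(build_ladder(1, 1, 3), class = "ndsynergy_invalid_parameter")
  expect_error(build_ladder(1, 2, 0), class = "ndsynergy_invalid_parameter")
})

test_that("design size accounting reports both conventions", {
  s <- design_size(8, 10)
  expect_identical(s$formula_count, 2560)
  expect_identical(s$unique_condition_count, 9 * 255 + 1)
  s1 <- design_size(1, 2)
  expect_identical(s1$formula_count, 4)
  expect_identical(s1$unique_condition_count, 2)

  expect_identical(full_factorial_size(8, 10), 1e8)
  expect_identical(full_factorial_size(1, 7), 7)
  expect_identical(full_factorial_size(3, 4), 64)
})

test_that("NDS enumeration covers every subset at every step", {
  # d = 2, 3 steps: 3 subsets x 3 steps + 1 control = 10 unique conditions
  p <- two_drug_mic_panel()
  d <- enumerate_nds(p, build_ladder(1, 2, 3))
  expect_equal(nrow(d), 10)
  expect_equal(sum(d$subset != ""), 9)

  # single drug reduces to a dilution series
  p1 <- generic_panel(1)
  d1 <- enumerate_nds(p1, build_ladder(1, 2, 5))
  expect_equal(nrow(d1), 6)

  # d = 3, 4 steps, duplicated: 7 x 4 x 2 = 56 drug points
  p3 <- generic_panel(3)
  d3 <- enumerate_nds(p3, build_ladder(1, 2, 4), replicates = 2)
  expect_equal(sum(d3$subset != ""), 56)
  expect_equal(sum(d3$subset == ""), 2)

  expect_error(enumerate_nds(p, build_ladder(1, 2, 3), replicates = 0),
               class = "ndsynergy_invalid_parameter")
})

test_that("every design point lies exactly on its subset diagonal", {
  p <- drug_panel(paste0("d", 1:3), c("A", "B", "C"),
                  mic = c(16, 0.25, 0.015625), normalization = "MIC")
  des <- enumerate_nds(p, build_ladder(1, 2, 6))
  drugs <- tibble::as_tibble(des)[des$subset != "", ]
  for (i in seq_len(nrow(drugs))) {
    row <- drugs[i, ]
    codes <- strsplit(row$subset, ";")[[1]]
    ratios <- vapply(codes, function(cd) {
      row[[cd]] / p$normalization[p$asm_code == cd]
    }, numeric(1))
    expect_identical(max(ratios), min(ratios))
    expect_identical(unname(max(ratios)), row$ratio)
    off <- setdiff(p$asm_code, codes)
    expect_true(all(unlist(row[off]) == 0))
  }
})

test_that("enumeration size matches the closed-form accounting", {
  for (d in 1:6) {
    for (steps in c(1, 4, 10)) {
      p <- generic_panel(d)
      des <- enumerate_nds(p, build_ladder(1, 2, steps))
      expect_equal(nrow(des), steps * (2^d - 1) + 1)
      # unique conditions equal the de-duplicated closed form (m = steps + 1)
      expect_equal(nrow(des), design_size(d, steps + 1)$unique_condition_count)
    }
  }
})

test_that("layout randomization is a seeded permutation with no well reused", {
  p <- generic_panel(3)
  des <- enumerate_nds(p, build_ladder(1, 2, 10), replicates = 2)
  a <- randomize_layout(des, wells_per_plate = 96, seed = 7)
  b <- randomize_layout(des, wells_per_plate = 96, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c2 <- randomize_layout(des, wells_per_plate = 96, seed = 8)
  expect_false(identical(a$well, c2$well))

  expect_false(any(duplicated(paste(a$plate, a$well))))
  expect_equal(length(unique(a$plate)), ceiling(nrow(des) / 96))

  # a 2560-point layout spans ceil(2560/96) = 27 plates
  expect_equal(ceiling(2560 / 96), 27)

  small <- randomize_layout(enumerate_nds(p, build_ladder(1, 2, 1)), seed = 1)
  expect_equal(length(unique(small$plate)), 1)
  expect_equal(length(unique(small$well)), nrow(small))
})

test_that("steps_between recovers dilution-gradient distances", {
  expect_equal(steps_between(0.25, 0.015625, 2), 4)
  expect_equal(steps_between(5, 5, 2), 0)
  expect_equal(steps_between(16, 8, 2), 1)
  expect_error(steps_between(-1, 2), class = "ndsynergy_invalid_parameter")
})

test_that("designs round-trip through CSV bit-exactly", {
  p <- drug_panel(paste0("d", 1:3), c("A", "B", "C"),
                  mic = c(16, 0.25, 0.015625), normalization = "MIC")
  des <- randomize_layout(enumerate_nds(p, build_ladder(1, 2, 10)), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design(des, path)
  back <- read_design(path, p)
  expect_identical(strip_attrs(back[, names(tibble::as_tibble(des))]),
                   strip_attrs(des))
  # writing the re-read design reproduces the same decimal text
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_design(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
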