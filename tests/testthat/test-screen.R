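mk_screen <- function(antis, senses = NULL, act = NULL) {
  df <- data.frame(antisense = antis, stringsAsFactors = FALSE)
  if (!is.null(senses)) df$sense <- senses
  df$activity <- if (is.null(act)) seq_along(antis) / 10 else act
  df
}

test_that("position-1 selection keeps only U/A guides, order preserved", {
  set.seed(43)
  tails <- replicate(4, random_seq(18))
  recs <- mk_screen(paste0(c("U", "A", "G", "C"), tails))
  sel <- select_high_confidence(recs)
  expect_equal(nrow(sel), 2L)
  expect_equal(substr(sel$antisense, 1, 1), c("U", "A"))
  s <- attr(sel, "summary")
  expect_equal(s$n_input, 4L)
  expect_equal(s$n_pos1, 2L)
  expect_equal(s$n_selected, 2L)
  empty <- select_high_confidence(recs[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
})

test_that("the strand-bias filter keeps antisense-favored duplexes only", {
  set.seed(47)
  t1 <- random_seq(13); t2 <- random_seq(13)
  strong_anti <- paste0("U", "GGGGG", t1)  # stable antisense nucleation
  weak_sense <- paste0("U", "AAAAA", t2)
  recs <- mk_screen(c(strong_anti, weak_sense),
                    senses = c(weak_sense, strong_anti))
  sel <- select_high_confidence(recs, require_ddg_negative = TRUE)
  expect_equal(sel$antisense, strong_anti)
  expect_error(select_high_confidence(mk_screen(strong_anti),
                                      require_ddg_negative = TRUE),
               "sense strands are required")
})

test_that("selection output is always a subset of its input", {
  set.seed(53)
  anti <- vapply(1:40, function(i) random_seq(19), "")
  recs <- mk_screen(anti, senses = rna_revcomp(anti))
  sel <- select_high_confidence(recs, require_ddg_negative = TRUE)
  expect_true(all(sel$antisense %in% recs$antisense))
  expect_lte(attr(sel, "summary")$n_selected, attr(sel, "summary")$n_pos1)
})

test_that("weighted family energies are frequency-weighted means", {
  expect_equal(weighted_family_energy(-7.2, 5), -7.2)
  expect_equal(weighted_family_energy(c(-10, -20), c(1, 1)), -15)
  expect_equal(weighted_family_energy(c(-10, -20), c(3, 1)), -12.5)
  expect_error(weighted_family_energy(c(-1, -2), c(0, 0)), "positive")
  set.seed(59)
  for (i in 1:25) {
    dg <- -runif(5, 1, 20)
    w <- runif(5)
    v <- weighted_family_energy(dg, w)
    expect_gte(v, min(dg)); expect_lte(v, max(dg))
  }
})

test_that("energy normalization linearizes the constructed relation", {
  set.seed(61)
  expr <- seq(2, 9, length.out = 12)
  dg <- -runif(12, 2, 10)
  rows <- data.frame(expression = expr,
                     site_count = (-dg) * (3 + 2 * expr), dg = dg)
  expect_equal(normalized_correlation(rows, "energy_normalized"), 1,
               tolerance = 1e-9)
  expect_lt(normalized_correlation(rows, "raw"), 1)
  # invariance to positive rescaling of the counts
  rows2 <- rows; rows2$site_count <- rows2$site_count * 7.3
  expect_equal(normalized_correlation(rows2, "energy_normalized"),
               normalized_correlation(rows, "energy_normalized"))
  expect_error(normalized_correlation(rows[1:2, ]), "3 rows")
  rows$dg[1] <- 0.5
  expect_error(normalized_correlation(rows, "energy_normalized"),
               "negative")
})

test_that("degenerate correlations are rejected", {
  rows <- data.frame(expression = c(1, 1, 1), site_count = c(1, 2, 3),
                     dg = c(-1, -2, -3))
  expect_error(normalized_correlation(rows, "raw"), "zero variance")
})

test_that("binned activities aggregate records by nucleation energy", {
  set.seed(67)
  a1 <- random_seq(19)
  single <- bin_activity_by_energy(mk_screen(a1, act = 0.4))
  expect_equal(nrow(single), 1L)
  expect_equal(single$n, 1L)
  expect_equal(single$mean_activity, 0.4)
  dup <- bin_activity_by_energy(mk_screen(c(a1, a1), act = c(0.2, 0.6)))
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$n, 2L)
  expect_equal(dup$mean_activity, 0.4)
  expect_error(bin_activity_by_energy(mk_screen(a1), bin_width = 0),
               "positive")
})

test_that("binned means recover the planted plateau of the synthetic screen", {
  scr <- synth_screen(fixture_spec(seed = 71, screen_n = 600))
  bins <- bin_activity_by_energy(scr, bin_width = 0.5)
  solid <- bins[bins$n >= 10, ]
  top <- solid[which.max(solid$mean_activity), ]
  truth <- attr(scr, "truth")
  expect_gte(top$bin_lo, truth$plateau_window[1] - 0.5)
  expect_lte(top$bin_hi, truth$plateau_window[2] + 0.5)
})
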