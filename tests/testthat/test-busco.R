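test_that("published category percentages are reproduced exactly", {
  counts <- delphinoidea_busco_counts()
  pct <- completeness_percentages(counts)
  top <- dplyr::filter(pct, species == "Phocoena sinus")
  expect_equal(top$pct_single, 98.68)
  expect_equal(top$pct_duplicated, 0.65)
  expect_equal(top$pct_missing, 0.48)
  expect_equal(top$pct_fragmented, 0.19)
  focal <- dplyr::filter(pct, species == "Lagenorhynchus cruciger")
  expect_equal(focal$pct_single, 98.55)
  expect_equal(focal$pct_duplicated, 0.78)
  expect_equal(focal$pct_missing, 0.39)
  expect_equal(focal$pct_fragmented, 0.28)
  # every row's percentages sum to 100 within rounding slack
  sums <- pct$pct_single + pct$pct_duplicated + pct$pct_missing +
    pct$pct_fragmented
  expect_true(all(abs(sums - 100) <= 0.03))
})

test_that("degenerate count rows behave", {
  one <- tibble::tibble(species = "x", single = 1L, duplicated = 0L,
                        missing = 0L, fragmented = 0L)
  expect_equal(completeness_percentages(one)$pct_single, 100.00)
  zero <- dplyr::mutate(one, single = 0L)
  expect_error(completeness_percentages(zero), "zero")
})

test_that("category means reproduce the published duplicated/fragmented values", {
  counts <- delphinoidea_busco_counts()
  dup <- category_means(counts, "duplicated")
  expect_equal(dup$mean_raw, 115.7)
  expect_equal(dup$mean_rounded, 116)
  frag <- category_means(counts, "fragmented")
  expect_equal(frag$mean_raw, 26.0)
  expect_equal(frag$mean_rounded, 26)
  # sum/n oracle
  expect_equal(dup$mean_raw, sum(counts$duplicated) / nrow(counts))
  # permutation invariance
  shuffled <- counts[sample(nrow(counts)), ]
  expect_equal(category_means(shuffled, "duplicated")$mean_raw, 115.7)
  # single species mean is its own value
  expect_equal(category_means(counts[1, ], "missing")$mean_raw, 59)
  expect_error(category_means(counts, "golden"), "unknown")
  # focal exclusion uses the named species
  dup_x <- category_means(counts, "duplicated", include_focal = FALSE,
                          focal = "Lagenorhynchus cruciger")
  expect_equal(dup_x$n_species, 9)
  expect_equal(dup_x$mean_raw, (sum(counts$duplicated) - 96) / 9)
})

test_that("upset cardinalities partition the BUSCO universe", {
  fix <- generate_busco_fixture(n_species = 6, n_busco = 400,
                                ancestral_missing = 12,
                                lineage_specific = list(
                                  list(n = 25, status = "single",
                                       species = sprintf("sp%02d", 1:5)),
                                  list(n = 7, status = "missing",
                                       species = sprintf("sp%02d", 5:6))),
                                seed = 91)
  for (st in c("single", "missing")) {
    up <- upset_intersections(fix$status_map, st)
    expect_equal(sum(up$n_busco), 400)
  }
  up_m <- upset_intersections(fix$status_map, "missing")
  expect_equal(dplyr::filter(up_m, n_species == 6)$n_busco, 12)
  expect_equal(dplyr::filter(up_m, n_species == 2)$n_busco, 7)
  # top_n truncates after ranking by cardinality
  up_top <- upset_intersections(fix$status_map, "single", top_n = 2)
  expect_equal(nrow(up_top), 2)
  expect_true(all(diff(up_top$n_busco) <= 0))
})

test_that("inconsistent BUSCO universes across species are rejected", {
  bad <- dplyr::bind_rows(
    tibble::tibble(species = "sp1", busco_id = c("b1", "b2"),
                   status = "single"),
    tibble::tibble(species = "sp2", busco_id = "b1", status = "single"))
  expect_error(upset_intersections(bad, "single"), "universes")
})

test_that("ancestral-loss adjustment reproduces the published 15 / 12,201", {
  counts <- delphinoidea_busco_counts()
  adj <- ancestral_missing_adjustment(counts, 33)
  focal <- dplyr::filter(adj$per_species,
                         species == "Lagenorhynchus cruciger")
  expect_equal(focal$adjusted_missing, 15)
  expect_equal(focal$adjusted_total, 12201)
  expect_equal(adj$adjusted_mean_missing, 26)
  # zero adjustment leaves the table unchanged
  adj0 <- ancestral_missing_adjustment(counts, 0)
  expect_equal(adj0$per_species$adjusted_missing, counts$missing)
  # infeasible adjustment: exceeds the orca's 41 missing
  expect_error(ancestral_missing_adjustment(counts, 45), "exceeds")
})
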