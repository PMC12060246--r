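make_callset_fixture <- function(seed = 31, ...) {
  gen <- generate_assembly(small_spec(seed = seed))
  ann <- generate_annotation(gen$assembly, gene_density = 40,
                             seed = seed + 1)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = seed + 2,
                             ...)
  list(gen = gen, ann = ann, calls = calls)
}

test_that("zero het rates leave only caller-specific errors", {
  spec <- small_spec(seed = 32,
                     het_snv_rate = c(autosomal = 0, sex = 0, collapsed = 0,
                                      contaminant = 0),
                     het_indel_rate = c(autosomal = 0, sex = 0, collapsed = 0,
                                        contaminant = 0))
  gen <- generate_assembly(spec)
  ann <- generate_annotation(gen$assembly, gene_density = 40, seed = 33)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 34)
  expect_equal(nrow(calls$a), 0)
  expect_equal(nrow(calls$b), 0)
  expect_equal(sum(calls$variant_truth$caller == "both"), 0)
})

test_that("widely separated quality modes are required", {
  fix <- make_callset_fixture(seed = 35)
  expect_error(
    simulate_callsets(fix$gen$assembly, fix$ann, fix$gen$truth, seed = 36,
                      quality_modes = list(a = list(error = c(25, 2),
                                                    true = c(30, 6)),
                                           b = list(error = c(12, 2.5),
                                                    true = c(38, 7)))),
    ">= 10")
})

test_that("quality histograms are bimodal with an interior valley", {
  fix <- make_callset_fixture(seed = 37)
  for (qs in list(fix$calls$a$qual, fix$calls$b$qual)) {
    h <- table(factor(round(qs), levels = min(round(qs)):max(round(qs))))
    # brute-force valley search between the two largest separated maxima
    counts <- as.numeric(h)
    peak1 <- which.max(counts)
    far <- which(abs(seq_along(counts) - peak1) >= 10)
    peak2 <- far[which.max(counts[far])]
    lo <- min(peak1, peak2); hi <- max(peak1, peak2)
    valley <- min(counts[(lo + 1):(hi - 1)])
    expect_lt(valley, 0.5 * min(counts[peak1], counts[peak2]))
  }
})

test_that("caller membership and error flags form a consistent truth", {
  fix <- make_callset_fixture(seed = 38)
  vt <- fix$calls$variant_truth
  # truth enumerates emitted variants exactly: both + a_only = caller a
  expect_equal(sum(vt$caller %in% c("both", "a_only")), nrow(fix$calls$a))
  expect_equal(sum(vt$caller %in% c("both", "b_only")), nrow(fix$calls$b))
  # no duplicated loci in truth
  expect_equal(anyDuplicated(paste(vt$contig, vt$pos)), 0)
  # errors are caller-specific by construction
  expect_true(all(vt$is_error == (vt$caller != "both")))
})

test_that("exonic indels are thinned and frameshifts thinned further", {
  # high indel rate so the exon counts are informative
  spec <- small_spec(seed = 39,
                     het_indel_rate = c(autosomal = 0.003, sex = 0.003,
                                        collapsed = 0, contaminant = 0))
  gen <- generate_assembly(spec)
  ann <- generate_annotation(gen$assembly, gene_density = 120, seed = 40)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 41)
  idx <- build_annotation_index(ann,
                                setNames(gen$truth$length,
                                         gen$truth$contig_id))
  summ <- annotation_summary(idx, sum(gen$truth$length))
  vt <- assign_regions(dplyr::filter(calls$variant_truth, !is_error,
                                     vtype != "snv"), idx)
  exonic_frac <- mean(vt$region == "exon")
  # indels should be clearly depleted in exons relative to exonic bp share
  expect_lt(exonic_frac, 0.6 * summ$exonic_fraction)
})

test_that("planted phase blocks appear as distinct PS values per contig", {
  fix <- make_callset_fixture(seed = 42)
  b <- fix$calls$b
  realized <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(b, !is.na(phase_set)), contig),
    k = dplyr::n_distinct(phase_set))
  merged <- dplyr::left_join(fix$calls$phase_truth, realized, by = "contig")
  expect_equal(merged$n_blocks, merged$k)
})

test_that("call sets are deterministic under the seed", {
  f1 <- make_callset_fixture(seed = 43)
  f2 <- make_callset_fixture(seed = 43)
  expect_identical(f1$calls$a, f2$calls$a)
  expect_identical(f1$calls$b, f2$calls$b)
})
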