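mk_var <- function(contig, pos, ref = "A", alt = "T", genotype = "0/1") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 vtype = contigqc:::variant_type(ref, alt), qual = 30,
                 genotype = genotype, phase_set = NA_integer_)
}

tiny_index <- function() {
  build_annotation_index(tiny_annotation(), c(c1 = 10000L))
}

test_that("anchors and region precedence follow the stated conventions", {
  idx <- tiny_index()
  # SNV at the exon boundary base is exonic (closed-interval inclusion)
  r <- assign_regions(mk_var("c1", c(150, 151, 50)), idx)
  expect_equal(r$region, c("exon", "intron", "intergenic"))
  expect_equal(r$anchor, r$pos)  # SNV anchor is the position itself
  # a deletion anchored at the last exon base alters the first intron base
  d <- assign_regions(mk_var("c1", 150, "AC", "A"), idx)
  expect_equal(d$anchor, 151L)
  expect_equal(d$region, "intron")
})

test_that("unknown contigs are counted intergenic with a warning", {
  idx <- tiny_index()
  expect_warning(r <- assign_regions(mk_var("cZ", 10), idx), "absent")
  expect_equal(r$region, "intergenic")
})

test_that("depletion folds reproduce the printed worked example", {
  # genome 0.853% exonic; exonic indel fraction 0.245% -> 3.5-fold
  expect_equal(depletion_fold(0.853, 0.245), 3.5)
  expect_equal(depletion_fold(0.00853, 0.00245), 3.5)
  # SNV analogue: 0.853 vs 0.551 -> 1.5
  expect_equal(depletion_fold(0.853, 0.551), 1.5)
})

test_that("partition summary counts conserve and depletion matches by hand", {
  idx <- tiny_index()
  summ <- annotation_summary(tiny_annotation(), 10000)
  recs <- dplyr::bind_rows(
    mk_var("c1", c(110, 120, 180)),          # 3 exonic SNVs
    mk_var("c1", 155),                        # intronic SNV
    mk_var("c1", c(500, 600, 700, 800)),      # intergenic SNVs
    mk_var("c1", 109, "AC", "A"),             # exonic indel (anchor 110)
    mk_var("c1", 900, "A", "AT"))             # intergenic indel
  p <- partition_by_annotation(recs, idx, summ)
  counts <- tidyr::pivot_wider(p$by_region, names_from = region,
                               values_from = n)
  expect_equal(sum(p$by_region$n), nrow(recs))
  snv_row <- dplyr::filter(p$depletion, class == "snv")
  expect_equal(snv_row$variant_exonic_fraction, 3 / 8)
  expect_equal(snv_row$depletion_fold,
               summ$exonic_fraction / (3 / 8))
  indel_row <- dplyr::filter(p$depletion, class == "indel")
  expect_equal(indel_row$variant_exonic_fraction, 1 / 2)
  g <- generics::glance(p)
  expect_equal(g$n_total, nrow(recs))
})

test_that("uniform random variants show no exonic depletion", {
  # toy genome: one gene covering half the contig, all of it exon
  ann <- tibble::tibble(
    contig = "c1", type = c("gene", "mRNA", "exon"),
    start = 1L, end = c(5000L, 5000L, 5000L), strand = "+",
    feature_id = c("g1", "m1", "e1"), parent = c(NA, "g1", "m1"))
  idx <- build_annotation_index(ann, c(c1 = 10000L))
  summ <- annotation_summary(ann, 10000)
  set.seed(71)
  recs <- mk_var("c1", sample.int(10000, 1000, replace = FALSE))
  p <- partition_by_annotation(recs, idx, summ)
  exonic_frac <- dplyr::filter(p$by_region, class == "snv",
                               region == "exon")$fraction
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(exonic_frac - 0.5), 3 * se)
  expect_lt(abs(dplyr::filter(p$depletion, class == "snv")$depletion_fold - 1),
            0.15)
})

test_that("indel frame spectrum separates preserving from disrupting", {
  idx <- tiny_index()
  recs <- dplyr::bind_rows(
    mk_var("c1", 110, "ACTG", "A"),     # -3 exonic, preserving
    mk_var("c1", 115, "A", "ATTTGGG"),  # +6 exonic, preserving
    mk_var("c1", 120, "AC", "A"),       # -1 exonic, disrupting
    mk_var("c1", 155, "A", "AT"),       # +1 intronic
    mk_var("c1", 600, "A", "ATT"))      # +2 intergenic
  fs <- indel_frame_spectrum(recs, idx)
  ex <- dplyr::filter(fs, region == "exon")
  expect_equal(ex$n_preserving, 2)
  expect_equal(ex$n_disrupting, 1)
  expect_equal(ex$ratio, 2)
  expect_equal(dplyr::filter(fs, region == "intron")$n_disrupting, 1)
  # SNVs are ignored entirely
  fs2 <- indel_frame_spectrum(mk_var("c1", 110), idx)
  expect_equal(sum(fs2$n_preserving + fs2$n_disrupting), 0)
})

test_that("frameshift suppression in the generator is recoverable", {
  spec <- small_spec(seed = 72,
                     het_indel_rate = c(autosomal = 0.004, sex = 0.004,
                                        collapsed = 0, contaminant = 0))
  gen <- generate_assembly(spec)
  ann <- generate_annotation(gen$assembly, gene_density = 150, seed = 73)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 74)
  idx <- build_annotation_index(ann, setNames(gen$truth$length,
                                              gen$truth$contig_id))
  truth_recs <- dplyr::filter(calls$variant_truth, !is_error)
  fs <- indel_frame_spectrum(truth_recs, idx)
  ex <- dplyr::filter(fs, region == "exon")
  intr <- dplyr::filter(fs, region == "intron")
  # exonic preserving:disrupting ratio should exceed the intronic ratio
  # by roughly the planted 5x suppression
  rel <- (ex$n_preserving / ex$n_disrupting) /
    (intr$n_preserving / intr$n_disrupting)
  expect_gt(rel, 2)
})

test_that("per-gene indel rates and length bins compute from first principles", {
  idx <- tiny_index()
  # gene g1 has 80 exonic bp; two exonic 1-bp indels -> 25 per kbp
  recs <- dplyr::bind_rows(
    mk_var("c1", 110, "AC", "A"),
    mk_var("c1", 130, "A", "AT"),
    mk_var("c1", 110, "ACTG", "A"),  # 3-bp indel ignored by the 1-bp stat
    mk_var("c1", 155, "A", "AT"))    # intronic ignored
  pg <- per_gene_indel_stats(recs, idx)
  expect_equal(pg$per_gene$n_indel1, 2L)
  expect_equal(pg$per_gene$rate_per_kbp, 2 / 0.08)
  expect_equal(pg$by_length_bin$length_bin, floor(log2(100)))
  # no indels -> all-zero rates
  pg0 <- per_gene_indel_stats(mk_var("c1", 500), idx)
  expect_equal(pg0$per_gene$n_indel1, 0L)
  expect_equal(pg0$per_gene$rate_per_kbp, 0)
})

test_that("uniform indel rates show no length-bin trend", {
  gen <- generate_assembly(small_spec(seed = 75))
  ann <- generate_annotation(gen$assembly, gene_density = 150, seed = 76)
  idx <- build_annotation_index(ann, setNames(gen$truth$length,
                                              gen$truth$contig_id))
  # place 1-bp insertions uniformly inside exon unions
  set.seed(77)
  ex <- idx$exons
  ex_tbl <- tibble::tibble(contig = as.character(GenomicRanges::seqnames(ex)),
                           start = BiocGenerics::start(ex),
                           end = BiocGenerics::end(ex))
  pos_pool <- do.call(c, lapply(seq_len(nrow(ex_tbl)), function(i) {
    p <- ex_tbl$start[i]:ex_tbl$end[i]
    setNames(p, rep(ex_tbl$contig[i], length(p)))
  }))
  sel <- sample(length(pos_pool), 400)
  recs <- tibble::tibble(contig = names(pos_pool)[sel],
                         pos = as.integer(pos_pool[sel]),
                         ref = "A", alt = "AT", vtype = "ins", qual = 30,
                         genotype = "0/1", phase_set = NA_integer_)
  pg <- per_gene_indel_stats(recs, idx)
  fit <- lm(rate_per_kbp ~ length_bin,
            data = dplyr::filter(pg$by_length_bin, exonic_kbp > 1))
  ci <- confint(fit)["length_bin", ]
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("SNP densities per class compute from counts and lengths", {
  labels <- tibble::tibble(contig_id = c("c1", "c2"),
                           label = c("autosomal", "sex_candidate"),
                           length = c(10000L, 10000L))
  recs <- dplyr::bind_rows(
    mk_var("c1", seq(101, by = 400, length.out = 24)),   # 24 SNVs on 10 kbp
    mk_var("c2", 5000))
  dens <- density_by_contig_class(recs, labels)
  auto <- dplyr::filter(dens$per_class, label == "autosomal")
  expect_equal(auto$snv_per_kbp, 2.4)
  sex <- dplyr::filter(dens$per_class, label == "sex_candidate")
  expect_equal(sex$snv_per_kbp, 0.1)
  # zero-variant input gives zero densities
  dens0 <- density_by_contig_class(recs[0, ], labels)
  expect_true(all(dens0$per_class$snv_per_kbp == 0))
  # labels must cover every contig carrying records
  expect_error(density_by_contig_class(mk_var("c9", 1), labels), "missing")
  # hets_only drops homozygous records
  hom <- mk_var("c1", 42, genotype = "1/1")
  d_hom <- density_by_contig_class(hom, labels)
  expect_equal(sum(d_hom$per_class$n_snv), 0)
})

test_that("the planted autosomal:sex density contrast is recovered", {
  gen <- generate_assembly(small_spec(seed = 78))
  ann <- generate_annotation(gen$assembly, gene_density = 40, seed = 79)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 80)
  labels <- dplyr::transmute(gen$truth, contig_id,
                             label = class, length)
  truth_recs <- dplyr::filter(calls$variant_truth, caller == "both") |>
    dplyr::mutate(qual = 30, genotype = "0/1", phase_set = NA_integer_)
  dens <- density_by_contig_class(truth_recs, labels)
  auto <- dplyr::filter(dens$per_class, label == "autosomal")$snv_per_kbp
  sex <- dplyr::filter(dens$per_class, label == "sex")$snv_per_kbp
  expect_lt(abs(auto - 2.4) / 2.4, 0.15)
  ratio <- auto / sex
  # planted contrast is 20x; allow generous sampling noise at this scale
  expect_gt(ratio, 12)
  expect_lt(ratio, 33)
})
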