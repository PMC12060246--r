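mk_rec <- function(contig, pos, ref, alt, qual = 30, genotype = "0/1") {
  tibble::tibble(contig = contig, pos = as.integer(pos), ref = ref,
                 alt = alt, vtype = contigqc:::variant_type(ref, alt),
                 qual = qual, genotype = genotype, phase_set = NA_integer_)
}

test_that("left alignment shifts a repeat-context deletion to the first copy", {
  #               1234567890
  seq <- c(c1 = "AACTCTCTGG")
  # a CT deletion reported mid-repeat must shift to the first repeat copy
  rec <- mk_rec("c1", 4, "TCT", "T")
  norm <- normalize_variants(rec, seq)
  oracle <- oracle_left_align(seq[["c1"]], 4, "TCT", "T")
  expect_equal(norm$pos, oracle$pos)
  expect_equal(norm$ref, oracle$ref)
  expect_equal(norm$alt, oracle$alt)
  expect_equal(norm$pos, 2L)  # first CT copy starts at 3; anchor at 2
})

test_that("normalization is idempotent and leaves minimal SNVs unchanged", {
  seq <- c(c1 = "ACGTACGTACGT")
  snv <- mk_rec("c1", 5, "A", "G")
  expect_equal(normalize_variants(snv, seq), snv)
  n1 <- normalize_variants(mk_rec("c1", 7, "GTA", "G"), seq)
  n2 <- normalize_variants(n1, seq)
  expect_equal(n1, n2)
})

test_that("multiallelic records split into biallelic ones", {
  seq <- c(c1 = "ACGTACGT")
  rec <- mk_rec("c1", 3, "G", "A,T")
  norm <- normalize_variants(rec, seq)
  expect_equal(nrow(norm), 2)
  expect_setequal(norm$alt, c("A", "T"))
  expect_equal(unique(norm$vtype), "snv")
})

test_that("shared prefix and suffix bases are trimmed", {
  seq <- c(c1 = "TTACGGACGT")
  # 'ACG' -> 'AG' at pos 3 is really a C deletion
  rec <- mk_rec("c1", 3, "ACG", "AG")
  norm <- normalize_variants(rec, seq)
  expect_equal(abs(nchar(norm$ref) - nchar(norm$alt)), 1)
  expect_equal(norm$vtype, "del")
})

test_that("reference mismatches are rejected", {
  expect_error(normalize_variants(mk_rec("c1", 2, "G", "T"),
                                  c(c1 = "AACGT")), "mismatch")
  expect_error(normalize_variants(mk_rec("cX", 2, "A", "T"),
                                  c(c1 = "AACGT")), "not in assembly")
})

test_that("normalization matches the exhaustive left-shift oracle on random indels", {
  set.seed(51)
  for (i in 1:60) {
    s <- oracle_random_dna(60)
    # build a repeat-rich region to stress shifting
    s <- paste0(substr(s, 1, 20), strrep(substr(s, 21, 24), 4),
                substr(s, 37, 60))
    p <- sample(10:30, 1)
    if (runif(1) < 0.5) {
      L <- sample(1:3, 1)
      ref <- substr(s, p, p + L)
      alt <- substr(s, p, p)
      if (grepl("[^ACGT]", ref)) next
    } else {
      ref <- substr(s, p, p)
      ins <- paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                          replace = TRUE), collapse = "")
      alt <- paste0(ref, ins)
    }
    if (ref == alt) next
    norm <- normalize_variants(mk_rec("c1", p, ref, alt),
                               c(c1 = s))
    oracle <- oracle_left_align(s, p, ref, alt)
    expect_equal(norm$pos, oracle$pos, label = sprintf("case %d pos", i))
    expect_equal(norm$ref, oracle$ref, label = sprintf("case %d ref", i))
    expect_equal(norm$alt, oracle$alt, label = sprintf("case %d alt", i))
  }
})

test_that("quality dip detection finds planted valleys and applies tie rules", {
  set.seed(52)
  # mixture with modes 8 and 30 and a valley near 14
  q <- c(rnorm(800, 8, 2), rnorm(2400, 30, 6.5))
  q <- pmin(60, pmax(1, round(q)))
  dip <- detect_quality_dip(q)
  # brute-force valley: smallest smoothed count strictly between the peaks
  expect_lte(abs(dip - 14), 1)
  # unimodal input falls back
  expect_equal(detect_quality_dip(round(rnorm(500, 30, 3)), fallback = 14L),
               14L)
  expect_error(detect_quality_dip(numeric(0)), "empty")
  expect_warning(detect_quality_dip(c(rep(5, 30), rep(40, 30))), "100")
})

test_that("flat valleys resolve to the leftmost minimal bin", {
  # two spikes with a perfectly flat zero valley
  q <- c(rep(5, 200), rep(40, 200))
  dip <- suppressWarnings(detect_quality_dip(q))
  # smoothing leaves bins 7..38 tied at zero; leftmost wins
  expect_equal(dip, 7L)
})

test_that("quality filtering is strictly greater-than", {
  recs <- mk_rec("c1", 1:3, "A", "T", qual = c(14, 14.5, 20))
  expect_equal(nrow(filter_by_quality(recs, 14)), 2)
  expect_equal(nrow(filter_by_quality(recs, 0)), 3)
  expect_error(filter_by_quality(recs, -1), ">= 0")
})

test_that("intersection splits identical, disjoint and partial call sets", {
  seq <- c(c1 = strrep("A", 500))
  a <- normalize_variants(mk_rec("c1", c(10, 20, 30), "A", "T"), seq)
  expect_error(intersect_callsets(a[c(2, 1, 3), ], a), "not sorted")
  isec <- intersect_callsets(a, a)
  expect_equal(nrow(isec$shared), 3)
  expect_equal(nrow(isec$a_only), 0)
  b <- dplyr::mutate(a, pos = pos + 1L)
  isec2 <- suppressWarnings(intersect_callsets(a, b))
  expect_equal(nrow(isec2$shared), 0)
  expect_equal(nrow(isec2$b_only), 3)
})

test_that("intersection counts are commutative and match a brute-force oracle", {
  set.seed(54)
  for (i in 1:40) {
    pos_a <- sort(sample.int(500, sample(5:40, 1)))
    pos_b <- sort(sample.int(500, sample(5:40, 1)))
    a <- tibble::tibble(contig = "c1", pos = pos_a, ref = "A", alt = "T",
                        vtype = "snv", qual = 30, genotype = "0/1",
                        phase_set = NA_integer_)
    b <- tibble::tibble(contig = "c1", pos = pos_b, ref = "A", alt = "T",
                        vtype = "snv", qual = 30, genotype = "0/1",
                        phase_set = NA_integer_)
    ab <- intersect_callsets(a, b)
    ba <- intersect_callsets(b, a)
    expect_equal(nrow(ab$shared), length(intersect(pos_a, pos_b)))
    expect_equal(nrow(ab$a_only), length(setdiff(pos_a, pos_b)))
    expect_equal(nrow(ab$shared), nrow(ba$shared))
  }
})

test_that("synthetic paired call sets intersect to exactly the truth", {
  gen <- generate_assembly(small_spec(seed = 55))
  ann <- generate_annotation(gen$assembly, gene_density = 40, seed = 56)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 57)
  a <- normalize_variants(calls$a, gen$assembly)
  b <- normalize_variants(calls$b, gen$assembly)
  isec <- intersect_callsets(a, b)
  truth_both <- dplyr::filter(calls$variant_truth, caller == "both")
  expect_equal(nrow(isec$shared), nrow(truth_both))
  # keys match exactly after normalizing the truth the same way
  tr <- normalize_variants(
    dplyr::mutate(truth_both, qual = 1, genotype = "0/1",
                  phase_set = NA_integer_), gen$assembly)
  expect_equal(paste(isec$shared$contig, isec$shared$pos, isec$shared$ref,
                     isec$shared$alt),
               paste(tr$contig, tr$pos, tr$ref, tr$alt))
})

test_that("filtering at the detected dip retains close to the true fraction", {
  gen <- generate_assembly(small_spec(seed = 58))
  ann <- generate_annotation(gen$assembly, gene_density = 40, seed = 59)
  calls <- simulate_callsets(gen$assembly, ann, gen$truth, seed = 60)
  dip <- detect_quality_dip(calls$a$qual)
  kept <- nrow(filter_by_quality(calls$a, dip)) / nrow(calls$a)
  true_frac <- sum(calls$variant_truth$caller == "both") /
    nrow(calls$a)
  expect_lt(abs(kept - true_frac), 0.02)
})
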