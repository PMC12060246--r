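test_that("identical sequences give identical sketches", {
  s <- oracle_random_dna(500, 101)
  a <- minhash_sketch(s, k = 21, sketch_size = 100)
  b <- minhash_sketch(s, k = 21, sketch_size = 100)
  expect_identical(a$hashes, b$hashes)
  expect_true(all(diff(a$hashes) > 0))  # ascending, distinct
  expect_lte(length(a$hashes), 100)
})

test_that("a saturated sketch is the full canonical k-mer hash set", {
  s <- oracle_random_dna(200, 102)
  full <- minhash_sketch(s, k = 11, sketch_size = 10000)
  expect_equal(length(full$hashes),
               length(oracle_kmer_set(s, 11)))
})

test_that("mash distance closed forms", {
  s <- oracle_random_dna(400, 103)
  a <- minhash_sketch(s, 21, 200)
  # j = 1 -> d = 0
  expect_equal(mash_distance(a, a), 0)
  # j = 0 -> capped at 1
  b <- minhash_sketch(oracle_random_dna(400, 104), 21, 200)
  # two independent 400-mers share essentially no 21-mers
  expect_equal(mash_distance(a, b), 1.0)
  # k mismatch is an error
  expect_error(mash_distance(a, minhash_sketch(s, 15, 200)), "mismatch")
})

test_that("the Mash transform evaluates the closed form at j = 0.5", {
  d <- -(1 / 21) * log(2 * 0.5 / (1 + 0.5))
  expect_equal(d, 0.019308, tolerance = 1e-4)
  # monotone decreasing in j
  j <- seq(0.05, 1, by = 0.05)
  dd <- -(1 / 21) * log(2 * j / (1 + j))
  expect_true(all(diff(dd) < 0))
})

test_that("sketch-estimated Jaccard is close to exact set Jaccard", {
  set.seed(105)
  for (i in 1:5) {
    base <- oracle_random_dna(3000)
    # overlapping halves create a known-sharing pair
    s1 <- substr(base, 1, 2000)
    s2 <- substr(base, 1001, 3000)
    k1 <- oracle_kmer_set(s1, 21)
    k2 <- oracle_kmer_set(s2, 21)
    exact_j <- length(intersect(k1, k2)) / length(union(k1, k2))
    sk1 <- minhash_sketch(s1, 21, 500)
    sk2 <- minhash_sketch(s2, 21, 500)
    est_j <- contigqc:::estimate_jaccard(sk1, sk2)
    se <- sqrt(exact_j * (1 - exact_j) / 500)
    expect_lte(abs(est_j - exact_j), 3 * se + 1e-9)
    # saturated sketches recover the exact Jaccard
    full1 <- minhash_sketch(s1, 21, 1e6)
    full2 <- minhash_sketch(s2, 21, 1e6)
    expect_equal(contigqc:::estimate_jaccard(full1, full2), exact_j,
                 tolerance = 1e-12)
    # symmetry
    expect_equal(mash_distance(sk1, sk2), mash_distance(sk2, sk1))
  }
})

test_that("contaminant screen recovers truth labels on a synthetic genome", {
  gen <- generate_assembly(small_spec(seed = 7))
  cfg <- threshold_config(sketch_size = 2000)
  ske <- minhash_sketch(gen$references$expected, 21, 2000)
  skc <- minhash_sketch(gen$references$contaminant, 21, 2000)
  scr <- contaminant_screen(gen$assembly, ske, skc, config = cfg)
  merged <- dplyr::left_join(scr, gen$truth, by = "contig_id")
  expect_true(all(merged$assignment[merged$class %in% c("autosomal", "sex")] ==
                    "expected"))
  expect_true(all(merged$assignment[merged$class == "contaminant"] ==
                    "contaminant_candidate"))
})

test_that("short contigs fall back to the longest-aligned-block rule", {
  gen <- generate_assembly(small_spec(seed = 8))
  cfg <- threshold_config(sketch_size = 500, small_contig_bp = 1e6)
  ske <- minhash_sketch(gen$references$expected, 21, 500)
  skc <- minhash_sketch(gen$references$contaminant, 21, 500)
  contigs <- gen$assembly[c(1, 8)]  # one host, one contaminant
  # PAF: host contig has its longest block on the expected reference;
  # the contaminant-derived contig on the contaminant reference
  paf <- tibble::tibble(
    query = c(names(contigs)[1], names(contigs)[1],
              names(contigs)[2], names(contigs)[2]),
    qlen = 10000L, qstart = 0L, qend = 5000L, strand = "+",
    target = c("expected", "contaminant", "expected", "contaminant"),
    tlen = 100000L, tstart = 0L, tend = 5000L, n_match = 4000L,
    block_len = c(9000L, 1400L, 1396L, 9000L), mapq = 60L)
  scr <- contaminant_screen(contigs, ske, skc, alignments = paf, config = cfg)
  expect_equal(scr$method, c("alignment", "alignment"))
  expect_equal(scr$assignment, c("expected", "contaminant_candidate"))
  # tie in block length, or no alignment at all -> unresolved
  paf_tie <- dplyr::mutate(paf, block_len = 5000L)
  scr_tie <- contaminant_screen(contigs, ske, skc, alignments = paf_tie,
                                config = cfg)
  expect_equal(unique(scr_tie$assignment), "unresolved")
  scr_none <- contaminant_screen(contigs, ske, skc, alignments = paf[0, ],
                                 config = cfg)
  expect_equal(unique(scr_none$assignment), "unresolved")
})

test_that("PAF reader enforces the 12-column format", {
  tf <- tempfile(fileext = ".paf")
  writeLines(c("q1\t100\t0\t50\t+\tt1\t200\t0\t50\t40\t50\t60",
               "q2\t100\t0\t50\t+\tt1\t200\t0\t50\t40\t50\t60\ttp:A:P"),
             tf)
  paf <- read_paf(tf)
  expect_equal(nrow(paf), 2)
  expect_equal(paf$block_len, c(50L, 50L))
  writeLines("q1\t100\t0\t50", tf)
  expect_error(read_paf(tf), "line 1")
})
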