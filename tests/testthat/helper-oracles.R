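# Brute-force oracles, kept independent of the package's implementation
# paths (plain string/table operations only).

oracle_random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# dictionary-count k-mer oracle (distinct k-mers, optionally canonical)
oracle_kmer_unique_fraction <- function(seq, k, canonical = TRUE) {
  seq <- toupper(seq)
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0) return(NA_real_)
  if (canonical) {
    rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
    kmers <- pmin(kmers, rc)
  }
  counts <- table(kmers)
  sum(counts == 1) / length(counts)
}

oracle_kmer_set <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  kmers <- substring(seq, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- vapply(kmers, oracle_revcomp, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rc))
}

# sort / cumulate / scan contiguity oracle
oracle_n50 <- function(lengths, half) {
  s <- sort(lengths, decreasing = TRUE)
  run <- 0
  for (i in seq_along(s)) {
    run <- run + s[i]
    if (run >= half) return(list(n = s[i], l = i))
  }
  list(n = NA_real_, l = NA_integer_)
}

# per-base pileup oracle by explicit tabulation
oracle_depth <- function(alignments, contig, contig_length, mapq_min) {
  depth <- integer(contig_length)
  keep <- alignments$contig == contig & alignments$mapq > mapq_min &
    bitwAnd(alignments$flag, 0x904L) == 0L
  a <- alignments[keep, , drop = FALSE]
  if (nrow(a) > 0) {
    for (i in seq_len(nrow(a))) {
      lo <- max(1L, a$pos[i])
      hi <- min(contig_length, a$pos[i] + a$read_len[i] - 1L)
      if (lo <= hi) depth[lo:hi] <- depth[lo:hi] + 1L
    }
  }
  depth
}

# exhaustive left-shift oracle: try every position left of the record and
# return the leftmost minimal indel representation that reproduces the same
# alternate haplotype
oracle_left_align <- function(seq, pos, ref, alt) {
  hap <- function(p, r, a) {
    paste0(substr(seq, 1, p - 1), a, substr(seq, p + nchar(r), nchar(seq)))
  }
  target <- hap(pos, ref, alt)
  L <- abs(nchar(ref) - nchar(alt))
  if (L == 0) return(list(pos = pos, ref = ref, alt = alt))
  is_del <- nchar(ref) > nchar(alt)
  for (p in seq_len(pos)) {
    if (is_del) {
      r <- substr(seq, p, p + L)
      if (nchar(r) < L + 1) next
      a <- substr(r, 1, 1)
    } else {
      r <- substr(seq, p, p)
      a <- substr(target, p, p + L)
      if (substr(a, 1, 1) != r) next
    }
    if (identical(hap(p, r, a), target)) {
      return(list(pos = p, ref = r, alt = a))
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

small_spec <- function(seed = 7, ...) {
  synth_spec(n_autosomal = 4, n_sex = 2, n_collapsed = 1, n_contaminant = 1,
             length_range = list(autosomal = c(40e3, 60e3),
                                 sex = c(30e3, 50e3),
                                 collapsed = c(20e3, 30e3),
                                 contaminant = c(12e3, 15e3)),
             seed = seed, ...)
}

tiny_annotation <- function() {
  tibble::tibble(
    contig = "c1",
    type = c("gene", "mRNA", "exon", "exon"),
    start = c(101L, 101L, 101L, 171L),
    end = c(200L, 200L, 150L, 200L),
    strand = "+",
    feature_id = c("g1", "m1", "m1.e1", "m1.e2"),
    parent = c(NA, "g1", "m1", "m1")
  )
}
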