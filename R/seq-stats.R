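#' GC content of a sequence
#'
#' Fraction (G+C)/(A+C+G+T), case-insensitive. `N` and other ambiguity codes
#' are excluded from both numerator and denominator, so soft- or hard-masked
#' input gives the same answer as unmasked input.
#'
#' @param sequence A single DNA string.
#' @return GC fraction, or `NA` if the sequence contains no unambiguous base.
#' @examples
#' gc_content("GGCC")
#' gc_content("ANGC")
#' @export
gc_content <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0) abort("empty sequence")
  up <- str_to_upper(sequence)
  gc <- str_count(up, "[GC]")
  at <- str_count(up, "[AT]")
  if (gc + at == 0) return(NA_real_)
  gc / (gc + at)
}

#' Masked fraction of a sequence
#'
#' Fraction of bases that are `N`/`n` (hard-masked) or lowercase a/c/g/t
#' (soft-masked), so either masking convention is recognised.
#'
#' @param sequence A single DNA string.
#' @return Fraction in \[0, 1\].
#' @examples
#' masked_fraction("AcgT")
#' @export
masked_fraction <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  n <- nchar(sequence)
  if (n == 0) abort("empty sequence")
  str_count(sequence, "[Nnacgt]") / n
}

#' Fraction of unique k-mers in a sequence
#'
#' Counts every k-mer of the sequence (case-insensitive; windows containing
#' non-ACGT characters are skipped) and returns the fraction of *distinct*
#' k-mers whose count is exactly one. With `canonical = TRUE` (default) a
#' k-mer and its reverse complement are collapsed to the lexicographically
#' smaller of the two, treating the genome as double-stranded.
#'
#' Collapsed repeats give themselves away here: a tandem array with period
#' shorter than `k` has almost no unique k-mers.
#'
#' @param sequence A single DNA string, length >= `k`.
#' @param k K-mer length (default 21).
#' @param canonical Collapse strands? Default `TRUE`.
#' @return Fraction of distinct k-mers seen exactly once, or `NA` if no
#'   window is free of ambiguity codes.
#' @examples
#' unique_kmer_fraction(strrep("A", 30), k = 21) # one distinct 21-mer, seen 10x
#' @export
unique_kmer_fraction <- function(sequence, k = 21L, canonical = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  k <- as.integer(k)
  if (k < 1L) abort("k must be >= 1")
  if (nchar(sequence) < k) abort("sequence shorter than k")
  .kmer_unique_fraction_cpp(sequence, k, canonical)
}

#' Telomere-motif count and enrichment for a contig
#'
#' Counts non-overlapping occurrences of `motif` and of its reverse
#' complement (case-insensitive) and expresses the per-bp motif density as a
#' fold enrichment over an assembly-wide baseline density. The vertebrate
#' telomeric repeat TTAGGG is the default motif; collapsed subtelomeric
#' contigs stand out as multi-fold enriched.
#'
#' @param sequence A single DNA string.
#' @param motif Motif to count (default `"TTAGGG"`).
#' @param assembly_baseline Baseline motif density in motifs/bp (e.g. from
#'   [telomere_baseline()]). `enrichment` is 0 when both baseline and count
#'   are 0 and `Inf` when the baseline is 0 but the motif occurs.
#' @return Tibble with columns `telomere_count`, `telomere_density`,
#'   `telomere_enrichment`.
#' @export
telomere_stats <- function(sequence, motif = "TTAGGG", assembly_baseline = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0) abort("empty sequence")
  if (nchar(motif) == 0) abort("empty motif")
  if (assembly_baseline < 0) abort("baseline must be >= 0")
  count <- count_motif_both_strands(sequence, motif)
  density <- count / nchar(sequence)
  enrichment <- if (assembly_baseline > 0) {
    density / assembly_baseline
  } else if (count == 0) 0 else Inf
  tibble(telomere_count = count, telomere_density = density,
         telomere_enrichment = enrichment)
}

# Non-overlapping motif count on both strands. If the motif is its own
# reverse complement the two scans would double-count, so it is counted once.
count_motif_both_strands <- function(sequence, motif) {
  up <- str_to_upper(sequence)
  m <- str_to_upper(motif)
  rc <- revcomp(m)
  n <- str_count(up, stringr::fixed(m))
  if (rc != m) n <- n + str_count(up, stringr::fixed(rc))
  n
}

#' Assembly-wide baseline motif density
#'
#' Total motif occurrences (both strands, non-overlapping) across all
#' sequences divided by total assembly length.
#'
#' @param seqs Named character vector of contig sequences.
#' @param motif Motif (default `"TTAGGG"`).
#' @return Density in motifs/bp.
#' @export
telomere_baseline <- function(seqs, motif = "TTAGGG") {
  total_len <- sum(nchar(seqs))
  if (total_len == 0) return(0)
  total <- sum(vapply(seqs, count_motif_both_strands, numeric(1),
                      motif = motif))
  total / total_len
}
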