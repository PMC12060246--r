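#' Per-contig diagnostic statistics
#'
#' One row per contig with the quantities used for triage: length, GC,
#' median depth at two MAPQ strata (all primary alignments, and alignments
#' with `mapq > mapq_min`), unique k-mer fraction, telomere-motif count and
#' fold enrichment over the assembly-wide baseline, and masked fraction.
#'
#' @param seqs Named character vector of contig sequences.
#' @param alignments Optional alignment tibble (see [read_sam()] /
#'   [simulate_alignments()]); depth columns are `NA` when absent.
#' @param k K-mer length for the uniqueness statistic (default 21).
#' @param mapq_min High-quality stratum keeps alignments with
#'   `mapq > mapq_min` (default 20, strict).
#' @param motif Telomere motif (default `"TTAGGG"`).
#' @param canonical Canonicalise k-mers (default `TRUE`).
#' @return Tibble with one row per contig.
#' @export
contig_stats <- function(seqs, alignments = NULL, k = 21L, mapq_min = 20L,
                         motif = "TTAGGG", canonical = TRUE) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  baseline <- telomere_baseline(seqs, motif)
  rows <- imap(seqs, function(s, id) {
    len <- nchar(s)
    tel <- telomere_stats(s, motif, baseline)
    tibble(
      contig_id = id,
      length = len,
      gc = gc_content(s),
      unique_kmer_fraction = if (len >= k) unique_kmer_fraction(s, k, canonical)
        else NA_real_,
      telomere_count = tel$telomere_count,
      telomere_enrichment = tel$telomere_enrichment,
      masked_fraction = masked_fraction(s)
    )
  })
  out <- list_rbind(rows)
  if (!is.null(alignments)) {
    lens <- setNames(nchar(seqs), names(seqs))
    depth_all <- map_dbl(names(seqs), function(id) {
      depth_profile(alignments, id, mapq_min = -1,
                    contig_length = lens[[id]])$median_depth
    })
    depth_hq <- map_dbl(names(seqs), function(id) {
      depth_profile(alignments, id, mapq_min = mapq_min,
                    contig_length = lens[[id]])$median_depth
    })
    out <- mutate(out, depth_all = depth_all, depth_hq = depth_hq,
                  .after = "gc")
  } else {
    out <- mutate(out, depth_all = NA_real_, depth_hq = NA_real_,
                  .after = "gc")
  }
  out
}
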