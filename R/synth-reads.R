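#' Simulate error-free read alignments at per-contig target depths
#'
#' Tiles error-free, ungapped reads at random positions so each contig's
#' realized depth lands within a few percent of its truth target (exactly
#' `round(depth * len / read_len)` reads of `read_len` reference bp each).
#' Reads from collapsed-class contigs are assigned MAPQ 0 with probability
#' `spec$collapsed_mapq0_prob` (ambiguous placement proxy), all other reads
#' MAPQ 60 -- the two MAPQ strata downstream diagnostics rely on.
#'
#' @param genome Named character vector of contig sequences.
#' @param truth Per-contig truth tibble from [generate_assembly()].
#' @param read_len Read length in bp (>= 50; reads never extend past contig
#'   ends).
#' @param seed Integer seed.
#' @param mapq0_prob Probability of MAPQ 0 for collapsed-contig reads.
#' @return Alignment tibble (`qname`, `flag`, `contig`, `pos`, `mapq`,
#'   `read_len`) with a `contig_lengths` attribute, ready for
#'   [write_sam()] or [depth_profile()].
#' @export
simulate_alignments <- function(genome, truth, read_len = 5000L, seed = 1L,
                                mapq0_prob = 0.95) {
  if (read_len < 50) abort("read_len must be >= 50")
  missing_ct <- setdiff(truth$contig_id, names(genome))
  if (length(missing_ct) > 0) {
    abort(sprintf("contig(s) in truth missing from genome: %s",
                  paste(head(missing_ct, 3), collapse = ", ")))
  }
  local_seed(seed, {
    rows <- pmap(list(truth$contig_id, truth$length, truth$target_depth,
                      truth$class),
                 function(id, len, depth, cl) {
      rl <- min(read_len, len)
      n_reads <- round(depth * len / rl)
      if (n_reads == 0) return(NULL)
      pos <- sample.int(len - rl + 1L, n_reads, replace = TRUE)
      mapq <- if (cl == "collapsed") {
        ifelse(runif(n_reads) < mapq0_prob, 0L, 60L)
      } else rep(60L, n_reads)
      tibble(qname = sprintf("%s_read_%06d", id, seq_len(n_reads)),
             flag = 0L, contig = id, pos = pos,
             mapq = mapq, read_len = rl)
    })
    out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
    if (nrow(out) == 0) {
      out <- tibble(qname = character(), flag = integer(),
                    contig = character(), pos = integer(), mapq = integer(),
                    read_len = integer())
    }
    attr(out, "contig_lengths") <- setNames(truth$length, truth$contig_id)
    out
  })
}
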