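#' Per-contig read-depth summary at a MAPQ stratum
#'
#' Computes per-base depth over the full contig length (uncovered bases count
#' as zero) from primary, non-supplementary alignments with MAPQ strictly
#' greater than `mapq_min`, and summarises it as median and mean. Two calls at
#' different strata (e.g. `mapq_min = -1` for all reads, `mapq_min = 20` for
#' high-quality mappers) expose collapsed repeats, which pile up all-read
#' depth but almost no confidently placed reads.
#'
#' @param alignments Alignment tibble (see [read_sam()]) with columns `flag`,
#'   `contig`, `pos`, `mapq`, `read_len`.
#' @param contig Contig to profile.
#' @param mapq_min Keep alignments with `mapq > mapq_min` (strict). Use `-1`
#'   to keep everything.
#' @param contig_length Length of the contig; taken from the
#'   `contig_lengths` attribute of `alignments` (set by [read_sam()] and
#'   [simulate_alignments()]) when `NULL`.
#' @return One-row tibble: `contig`, `mapq_min`, `median_depth`, `mean_depth`.
#'   Median over an even count is the mean of the central pair.
#' @export
depth_profile <- function(alignments, contig, mapq_min = -1,
                          contig_length = NULL) {
  if (is.null(contig_length)) {
    lens <- attr(alignments, "contig_lengths")
    if (is.null(lens) || !contig %in% names(lens)) {
      abort(sprintf("contig '%s' absent from header information", contig))
    }
    contig_length <- lens[[contig]]
  }
  depth <- depth_per_base(alignments, contig, mapq_min, contig_length)
  tibble(contig = contig, mapq_min = mapq_min,
         median_depth = median(depth), mean_depth = mean(depth))
}

# Per-base depth vector for one contig at one MAPQ stratum.
depth_per_base <- function(alignments, contig, mapq_min, contig_length) {
  keep <- alignments$contig == contig &
    alignments$mapq > mapq_min &
    bitwAnd(alignments$flag, 0x904L) == 0L  # mapped, primary, non-supplementary
  a <- alignments[keep, , drop = FALSE]
  if (nrow(a) == 0) return(integer(contig_length))
  ir <- IRanges::IRanges(start = a$pos, width = a$read_len)
  ir <- IRanges::restrict(ir, start = 1L, end = as.integer(contig_length))
  as.integer(IRanges::coverage(ir, width = as.integer(contig_length)))
}
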