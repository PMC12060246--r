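#' Assembly contiguity metrics (N50, NG50, L50)
#'
#' N50 is the length of the contig at which the cumulative sorted-descending
#' length first reaches half the assembly length; NG50 uses half of an
#' assumed genome size instead and is `NA` when the assembly does not reach
#' it; L50 is the rank of the N50 contig.
#'
#' @param lengths Positive contig lengths in bp.
#' @param genome_size_assumed Assumed genome size in bp for NG50 (e.g.
#'   2.384e9 for a delphinid nuclear genome); `NULL` skips NG50.
#' @return One-row tibble: `n_contigs`, `total_length`, `min_len`, `max_len`,
#'   `n50`, `ng50`, `l50`, `genome_size_assumed`.
#' @examples
#' assembly_metrics(c(50, 30, 20), genome_size_assumed = 100)
#' @export
assembly_metrics <- function(lengths, genome_size_assumed = NULL) {
  if (length(lengths) == 0) abort("empty length list")
  if (any(lengths <= 0)) abort("contig lengths must be > 0")
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  cs <- cumsum(s)
  total <- cs[length(cs)]
  i50 <- which(cs >= total / 2)[1]
  ng50 <- NA_real_
  if (!is.null(genome_size_assumed)) {
    ig <- which(cs >= genome_size_assumed / 2)
    if (length(ig) > 0) ng50 <- s[ig[1]]
  }
  tibble(
    n_contigs = length(lengths),
    total_length = total,
    min_len = min(s),
    max_len = max(s),
    n50 = s[i50],
    ng50 = ng50,
    l50 = as.integer(i50),
    genome_size_assumed = genome_size_assumed %||% NA_real_
  )
}
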