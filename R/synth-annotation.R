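#' Generate a synthetic gene annotation
#'
#' Places non-overlapping gene models (gene, mRNA, exons) along each contig
#' at a target gene density. Exon and intron lengths are drawn around
#' mammalian-like means (exons ~156 bp, introns ~1.6 kbp). A drawn gene
#' that cannot fit in the remaining contig space is re-drawn once and then
#' skipped, so short contigs simply carry fewer genes. Coordinates are
#' 1-based inclusive, GFF3 convention.
#'
#' @param genome Named character vector of contig sequences.
#' @param gene_density Genes per Mbp (> 0). The default 9 genes/Mbp with the
#'   default exon/intron means yields a genome that is ~0.8% exonic and
#'   ~6.6% intronic, the proportions typical of an annotated delphinid
#'   assembly.
#' @param exon_count_range `c(min, max)` exons per gene.
#' @param seed Integer seed.
#' @param mean_exon_len,mean_intron_len Mean feature lengths in bp.
#' @return Annotation tibble (`contig`, `type`, `start`, `end`, `strand`,
#'   `feature_id`, `parent`) ready for [write_gff3()] or
#'   [build_annotation_index()].
#' @export
generate_annotation <- function(genome, gene_density = 9,
                                exon_count_range = c(3L, 8L), seed = 1L,
                                mean_exon_len = 156, mean_intron_len = 1605) {
  if (gene_density <= 0) abort("gene_density must be > 0")
  local_seed(seed, {
    gene_counter <- 0L
    per_contig <- imap(genome, function(s, ctg) {
      len <- nchar(s)
      n_genes <- round(gene_density * len / 1e6)
      if (n_genes == 0) return(NULL)

      draw_gene <- function() {
        n_exons <- sample(exon_count_range[1]:exon_count_range[2], 1)
        exon_lens <- pmax(50L, as.integer(round(
          rnorm(n_exons, mean_exon_len, mean_exon_len / 4))))
        intron_lens <- if (n_exons > 1) {
          pmax(100L, as.integer(round(
            rnorm(n_exons - 1, mean_intron_len, mean_intron_len / 4))))
        } else integer(0)
        list(exon_lens = exon_lens, intron_lens = intron_lens,
             span = sum(exon_lens) + sum(intron_lens))
      }

      rows <- list()
      cursor <- 1L
      mean_span <- mean_exon_len * mean(exon_count_range) +
        mean_intron_len * (mean(exon_count_range) - 1)
      mean_gap <- max(200, len / n_genes - mean_span)
      for (g in seq_len(n_genes)) {
        gene <- draw_gene()
        if (cursor + gene$span - 1L > len) {
          gene <- draw_gene()  # retry once, then skip
          if (cursor + gene$span - 1L > len) next
        }
        gene_counter <<- gene_counter + 1L
        gid <- sprintf("gene_%05d", gene_counter)
        tid <- sprintf("mrna_%05d", gene_counter)
        start <- cursor
        end <- start + gene$span - 1L
        exon_starts <- start +
          cumsum(c(0L, head(gene$exon_lens, -1) + gene$intron_lens))
        exon_ends <- exon_starts + gene$exon_lens - 1L
        strand <- sample(c("+", "-"), 1)
        rows[[length(rows) + 1L]] <- bind_rows(
          tibble(contig = ctg, type = "gene", start = start, end = end,
                 strand = strand, feature_id = gid, parent = NA_character_),
          tibble(contig = ctg, type = "mRNA", start = start, end = end,
                 strand = strand, feature_id = tid, parent = gid),
          tibble(contig = ctg, type = "exon",
                 start = as.integer(exon_starts),
                 end = as.integer(exon_ends), strand = strand,
                 feature_id = sprintf("%s.exon%02d", tid,
                                      seq_along(exon_starts)),
                 parent = tid)
        )
        gap <- as.integer(round(runif(1, mean_gap * 0.3, mean_gap * 1.7)))
        cursor <- end + 1L + max(1L, gap)
        if (cursor > len) break
      }
      if (length(rows) == 0) NULL else list_rbind(rows)
    })
    out <- list_rbind(per_contig[!vapply(per_contig, is.null, logical(1))])
    if (is.null(out) || nrow(out) == 0) {
      out <- tibble(contig = character(), type = character(),
                    start = integer(), end = integer(), strand = character(),
                    feature_id = character(), parent = character())
    }
    out
  })
}
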