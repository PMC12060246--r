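#' Build an interval index from a gene annotation
#'
#' Resolves the gene/transcript/exon parent chain of a GFF3-style annotation
#' into reduced interval sets: the exon union, introns (gene spans minus
#' exons), genic union and, when contig lengths are supplied, the intergenic
#' complement. Exons falling outside their gene's span are rejected.
#'
#' @param annotation Annotation tibble (see [read_gff3()]) with columns
#'   `contig`, `type`, `start`, `end`, `feature_id`, `parent`.
#' @param contig_lengths Optional named vector of contig lengths; required
#'   for intergenic accounting over a concrete genome.
#' @return An `annotation_index` object: list with GRanges `exons`,
#'   `introns`, `genic`, per-gene tibble `genes`, per-transcript intron
#'   stats, and `contig_lengths`.
#' @export
build_annotation_index <- function(annotation, contig_lengths = NULL) {
  stopifnot(all(c("contig", "type", "start", "end") %in% names(annotation)))
  genes <- filter(annotation, .data$type == "gene")
  exons <- filter(annotation, .data$type == "exon")

  # exon -> gene through the (optional) transcript layer
  parent_of <- setNames(annotation$parent, annotation$feature_id)
  type_of <- setNames(annotation$type, annotation$feature_id)
  gene_of <- function(pid) {
    if (is.na(pid)) return(NA_character_)
    if (!is.na(type_of[pid]) && type_of[pid] == "gene") return(pid)
    gp <- parent_of[pid]
    if (!is.na(gp) && !is.na(type_of[gp]) && type_of[gp] == "gene") return(unname(gp))
    NA_character_
  }
  exon_gene <- vapply(exons$parent, gene_of, character(1))

  if (nrow(exons) > 0 && nrow(genes) > 0) {
    gs <- genes[match(exon_gene, genes$feature_id), ]
    bad <- which(!is.na(exon_gene) &
                   (exons$start < gs$start | exons$end > gs$end |
                      exons$contig != gs$contig))
    if (length(bad) > 0) {
      abort(sprintf("exon '%s' lies outside the span of its gene '%s'",
                    exons$feature_id[bad[1]], exon_gene[bad[1]]))
    }
  }

  as_gr <- function(tbl) {
    GenomicRanges::GRanges(tbl$contig, IRanges::IRanges(tbl$start, tbl$end))
  }
  exon_gr <- if (nrow(exons)) GenomicRanges::reduce(as_gr(exons)) else
    GenomicRanges::GRanges()
  gene_gr <- if (nrow(genes)) GenomicRanges::reduce(as_gr(genes)) else
    GenomicRanges::GRanges()
  intron_gr <- GenomicRanges::setdiff(gene_gr, exon_gr)

  # per-gene exonic bp for per-gene indel rates
  gene_tbl <- if (nrow(genes)) {
    exon_by_gene <- exons |>
      mutate(gene_id = exon_gene) |>
      filter(!is.na(.data$gene_id)) |>
      group_by(.data$gene_id) |>
      summarise(exonic_bp = sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(.data$start, .data$end)))), .groups = "drop")
    genes |>
      transmute(gene_id = .data$feature_id, contig = .data$contig,
                start = .data$start, end = .data$end,
                span = .data$end - .data$start + 1L) |>
      left_join(exon_by_gene, by = "gene_id") |>
      mutate(exonic_bp = coalesce(.data$exonic_bp, 0L))
  } else {
    tibble(gene_id = character(), contig = character(), start = integer(),
           end = integer(), span = integer(), exonic_bp = integer())
  }

  # per-transcript intron lengths (gaps between consecutive exons)
  intron_lens <- if (nrow(exons)) {
    exons |>
      filter(!is.na(.data$parent)) |>
      group_by(.data$parent) |>
      arrange(.data$start, .by_group = TRUE) |>
      summarise(gaps = list(if (n() > 1) .data$start[-1] - .data$end[-n()] - 1L
                            else integer()), .groups = "drop") |>
      pull(.data$gaps) |>
      unlist()
  } else integer()
  intron_lens <- intron_lens[intron_lens > 0]

  structure(
    list(exons = exon_gr, introns = intron_gr, genic = gene_gr,
         genes = gene_tbl, exon_tbl = exons, n_exons = nrow(exons),
         intron_lengths = intron_lens, contig_lengths = contig_lengths),
    class = "annotation_index"
  )
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("<annotation_index>\n")
  cat("  genes:", nrow(x$genes), " exon union bp:",
      sum(IRanges::width(x$exons)), " intron bp:",
      sum(IRanges::width(x$introns)), "\n")
  invisible(x)
}

#' Genome-fraction summary of an annotation
#'
#' Exonic bp is the union of exon intervals (overlaps counted once);
#' intronic bp is the union of gene spans minus the exon union; everything
#' else is intergenic. Fractions are taken over `genome_length`.
#'
#' @param annotation Annotation tibble, or an `annotation_index`.
#' @param genome_length Total genome length in bp.
#' @return One-row tibble with bp and fractions per region plus feature
#'   counts and mean lengths.
#' @export
annotation_summary <- function(annotation, genome_length) {
  idx <- if (inherits(annotation, "annotation_index")) annotation else
    build_annotation_index(annotation)
  exonic_bp <- sum(IRanges::width(idx$exons))
  intronic_bp <- sum(IRanges::width(idx$introns))
  genic_bp <- sum(IRanges::width(idx$genic))
  intergenic_bp <- genome_length - genic_bp
  tibble(
    genome_length = genome_length,
    exonic_bp = exonic_bp,
    intronic_bp = intronic_bp,
    intergenic_bp = intergenic_bp,
    exonic_fraction = exonic_bp / genome_length,
    intronic_fraction = intronic_bp / genome_length,
    intergenic_fraction = intergenic_bp / genome_length,
    n_genes = nrow(idx$genes),
    n_exons = idx$n_exons,
    n_introns = length(idx$intron_lengths),
    mean_gene_len = if (nrow(idx$genes)) mean(idx$genes$span) else NA_real_,
    mean_exon_len = if (idx$n_exons)
      mean(idx$exon_tbl$end - idx$exon_tbl$start + 1) else NA_real_,
    mean_intron_len = if (length(idx$intron_lengths))
      mean(idx$intron_lengths) else NA_real_
  )
}

# Region of each 1-based position: exon takes precedence over intron,
# intron over intergenic. Positions on unknown contigs are intergenic.
region_of_positions <- function(index, contig, pos) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L))
  region <- rep("intergenic", length(gr))
  # seqlevel-mismatch warnings are expected here: positions on contigs the
  # annotation has never seen are intergenic by definition
  ov_in <- suppressWarnings(IRanges::overlapsAny(gr, index$introns))
  region[ov_in] <- "intron"
  ov_ex <- suppressWarnings(IRanges::overlapsAny(gr, index$exons))
  region[ov_ex] <- "exon"
  region
}
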