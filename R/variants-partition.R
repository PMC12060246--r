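#' Assign each variant to exon, intron or intergenic space
#'
#' A variant's anchor is the first altered base: the record position for a
#' SNV, the base after it for a normalized indel. Exon takes precedence
#' over intron where features overlap. Variants on contigs absent from the
#' annotation's genome are counted intergenic with a warning.
#'
#' @param records Normalized variant tibble.
#' @param index An [build_annotation_index()] result.
#' @return `records` with `anchor` and `region` columns.
#' @export
assign_regions <- function(records, index) {
  if (nrow(records) == 0) {
    return(mutate(records, anchor = integer(0), region = character(0)))
  }
  if (!is.null(index$contig_lengths)) {
    unknown <- setdiff(unique(records$contig), names(index$contig_lengths))
    if (length(unknown) > 0) {
      warn(sprintf("%d contig(s) absent from annotation genome, counted intergenic: %s",
                   length(unknown), paste(head(unknown, 3), collapse = ", ")))
    }
  }
  records |>
    mutate(anchor = .data$pos + as.integer(.data$vtype != "snv"),
           region = region_of_positions(index, .data$contig, .data$anchor))
}

#' Partition a call set by annotation and quantify exonic depletion
#'
#' Counts variants per region and per variant class (SNV vs indel), and
#' computes the exonic depletion fold per class: the genome's exonic
#' fraction divided by the class's exonic variant fraction. Purifying
#' selection shows up as folds above 1, strongest for indels.
#'
#' @param records Normalized variant tibble.
#' @param index An [build_annotation_index()] result.
#' @param summary An [annotation_summary()] row for the same genome.
#' @return A `partition_summary`: list with `by_region` (counts/fractions
#'   per class and region), `depletion` (per class), and `genome` fractions.
#' @export
partition_by_annotation <- function(records, index, summary) {
  with_region <- assign_regions(records, index)
  classed <- mutate(with_region,
                    class = if_else(.data$vtype == "snv", "snv", "indel"))
  by_region <- classed |>
    count(.data$class, .data$region) |>
    tidyr::complete(class = c("snv", "indel"),
                    region = c("exon", "intron", "intergenic"),
                    fill = list(n = 0L)) |>
    group_by(.data$class) |>
    mutate(fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else 0) |>
    ungroup()
  depletion <- by_region |>
    filter(.data$region == "exon") |>
    transmute(
      class = .data$class,
      genome_exonic_fraction = summary$exonic_fraction,
      variant_exonic_fraction = .data$fraction,
      depletion_fold = if_else(.data$fraction > 0,
                               summary$exonic_fraction / .data$fraction,
                               NA_real_),
      depletion_fold_rounded = round_half_up(.data$depletion_fold, 1)
    )
  structure(list(by_region = by_region, depletion = depletion,
                 genome = summary, n_total = nrow(records)),
            class = "partition_summary")
}

#' @export
print.partition_summary <- function(x, ...) {
  cat("<partition_summary>", x$n_total, "variants\n")
  print(x$by_region)
  print(x$depletion)
  invisible(x)
}

#' @rdname partition_by_annotation
#' @param x A `partition_summary`.
#' @param ... Unused.
#' @export
tidy.partition_summary <- function(x, ...) x$by_region

#' @rdname partition_by_annotation
#' @export
glance.partition_summary <- function(x, ...) {
  x$depletion |>
    select("class", "depletion_fold") |>
    tidyr::pivot_wider(names_from = "class", values_from = "depletion_fold",
                       names_glue = "depletion_fold_{class}") |>
    mutate(n_total = x$n_total)
}

#' Exonic depletion fold from printed fractions
#'
#' The worked-example arithmetic: genome exonic fraction divided by variant
#' exonic fraction, e.g. `depletion_fold(0.853, 0.245)` on percentage
#' scales gives the familiar 3.5-fold indel depletion.
#'
#' @param genome_exonic_fraction Fraction (or percentage) of the genome that
#'   is exonic.
#' @param variant_exonic_fraction Fraction (or percentage, same scale) of
#'   variants that are exonic.
#' @param digits Rounding for the reported fold (default 1 decimal).
#' @return Rounded depletion fold.
#' @export
depletion_fold <- function(genome_exonic_fraction, variant_exonic_fraction,
                           digits = 1) {
  round_half_up(genome_exonic_fraction / variant_exonic_fraction, digits)
}

#' Indel frame spectrum by region
#'
#' Counts frame-preserving (length divisible by 3) vs frame-disrupting
#' indels per region. Coding exons under selection are depleted for
#' frame-disrupting indels; introns are not.
#'
#' @param records Normalized variant tibble.
#' @param index An [build_annotation_index()] result.
#' @return Tibble: `region`, `n_preserving`, `n_disrupting`, `ratio`
#'   (preserving / disrupting, `NA` when no disrupting indels).
#' @export
indel_frame_spectrum <- function(records, index) {
  indels <- filter(records, .data$vtype %in% c("ins", "del"))
  indels <- assign_regions(indels, index)
  indels |>
    mutate(indel_len = abs(nchar(.data$ref) - nchar(.data$alt)),
           preserving = .data$indel_len %% 3L == 0L) |>
    group_by(.data$region) |>
    summarise(n_preserving = sum(.data$preserving),
              n_disrupting = sum(!.data$preserving), .groups = "drop") |>
    tidyr::complete(region = c("exon", "intron", "intergenic"),
                    fill = list(n_preserving = 0L, n_disrupting = 0L)) |>
    mutate(ratio = if_else(.data$n_disrupting > 0,
                           .data$n_preserving / .data$n_disrupting, NA_real_))
}

#' Per-gene exonic 1-bp indel counts and rates
#'
#' Counts exonic single-base indels per gene and expresses them per exonic
#' kbp, plus a summary over log2 gene-length bins to expose rate-vs-length
#' trends (a uniform mutational process shows none; pseudogene-rich short
#' genes show elevated rates).
#'
#' @param records Normalized variant tibble.
#' @param index An [build_annotation_index()] result (supplies gene spans
#'   and per-gene exonic bp).
#' @return List of tibbles `per_gene` (`gene_id`, `span`, `exonic_bp`,
#'   `n_indel1`, `rate_per_kbp`) and `by_length_bin`.
#' @export
per_gene_indel_stats <- function(records, index) {
  genes <- index$genes
  if (any(genes$span <= 0)) abort("zero-length gene in annotation")
  indel1 <- records |>
    filter(.data$vtype %in% c("ins", "del"),
           abs(nchar(.data$ref) - nchar(.data$alt)) == 1L) |>
    assign_regions(index) |>
    filter(.data$region == "exon")
  counts <- if (nrow(indel1) > 0 && nrow(genes) > 0) {
    gr_pos <- GenomicRanges::GRanges(indel1$contig,
                                     IRanges::IRanges(indel1$anchor, width = 1L))
    gr_gene <- GenomicRanges::GRanges(genes$contig,
                                      IRanges::IRanges(genes$start, genes$end))
    hit <- GenomicRanges::findOverlaps(gr_pos, gr_gene, select = "first")
    tibble(gene_id = genes$gene_id[hit]) |>
      filter(!is.na(.data$gene_id)) |>
      count(.data$gene_id, name = "n_indel1")
  } else {
    tibble(gene_id = character(), n_indel1 = integer())
  }
  per_gene <- genes |>
    left_join(counts, by = "gene_id") |>
    mutate(n_indel1 = coalesce(.data$n_indel1, 0L),
           rate_per_kbp = if_else(.data$exonic_bp > 0,
                                  .data$n_indel1 / (.data$exonic_bp / 1000),
                                  NA_real_)) |>
    select("gene_id", "contig", "span", "exonic_bp", "n_indel1",
           "rate_per_kbp")
  by_length_bin <- per_gene |>
    mutate(length_bin = floor(log2(.data$span))) |>
    group_by(.data$length_bin) |>
    summarise(n_genes = n(),
              n_indel1 = sum(.data$n_indel1),
              exonic_kbp = sum(.data$exonic_bp) / 1000,
              rate_per_kbp = if_else(exonic_kbp > 0,
                                     sum(.data$n_indel1) / exonic_kbp,
                                     NA_real_),
              .groups = "drop")
  list(per_gene = per_gene, by_length_bin = by_length_bin)
}

#' SNP density by contig class
#'
#' Per class: total SNVs divided by total class length, in SNPs/kbp; plus
#' per-contig densities for dispersion. By default only heterozygous
#' genotypes are counted, matching the heterozygosity-per-kbp reading of
#' these densities.
#'
#' @param records Variant tibble.
#' @param labels Contig label tibble from [classify_contigs()] (must carry
#'   `contig_id`, `label`, `length` and cover every contig in `records`).
#' @param hets_only Count only heterozygous genotypes (default `TRUE`).
#' @return List of tibbles `per_class` and `per_contig`.
#' @export
density_by_contig_class <- function(records, labels, hets_only = TRUE) {
  missing_ct <- setdiff(unique(records$contig), labels$contig_id)
  if (length(missing_ct) > 0) {
    abort(sprintf("labels missing for contig(s): %s",
                  paste(head(missing_ct, 3), collapse = ", ")))
  }
  snvs <- filter(records, .data$vtype == "snv")
  if (hets_only && "genotype" %in% names(records)) {
    snvs <- filter(snvs, .data$genotype %in% c("0/1", "0|1", "1|0", "1/0"))
  }
  per_contig <- labels |>
    select("contig_id", "label", "length") |>
    left_join(count(snvs, contig_id = .data$contig, name = "n_snv"),
              by = "contig_id") |>
    mutate(n_snv = coalesce(.data$n_snv, 0L),
           snv_per_kbp = .data$n_snv / (.data$length / 1000))
  per_class <- per_contig |>
    group_by(.data$label) |>
    summarise(n_contigs = n(), n_snv = sum(.data$n_snv),
              total_bp = sum(.data$length),
              snv_per_kbp = sum(.data$n_snv) / (sum(.data$length) / 1000),
              .groups = "drop")
  list(per_class = per_class, per_contig = per_contig)
}
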