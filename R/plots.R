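#' Depth vs GC diagnostic plot
#'
#' The classic triage scatter: per-contig GC against median depth (choose
#' the stratum), points sized by log contig length and coloured by unique
#' k-mer fraction (or by label when a label tibble is supplied). Collapsed
#' repeats separate on colour, sex-linked contigs on the depth axis.
#'
#' @param stats Per-contig statistics from [contig_stats()].
#' @param stratum `"depth_hq"` (default) or `"depth_all"`.
#' @param labels Optional label tibble from [classify_contigs()].
#' @return A ggplot object.
#' @export
plot_depth_gc <- function(stats, stratum = c("depth_hq", "depth_all"),
                          labels = NULL) {
  stratum <- match.arg(stratum)
  dat <- stats
  if (!is.null(labels)) {
    dat <- left_join(dat, select(labels, "contig_id", "label"),
                     by = "contig_id")
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$gc * 100,
                                         y = .data[[stratum]])) +
    ggplot2::geom_point(ggplot2::aes(
      size = log10(.data$length),
      colour = if (is.null(labels)) .data$unique_kmer_fraction else
        .data$label), alpha = 0.8) +
    ggplot2::labs(x = "GC (%)", y = sprintf("median depth (%s)", stratum),
                  colour = if (is.null(labels)) "unique k-mer fraction" else
                    "label",
                  size = "log10 length")
  if (stratum == "depth_all") p <- p + ggplot2::scale_y_log10()
  p
}

#' Masked fraction vs depth plot
#'
#' @param stats Per-contig statistics from [contig_stats()].
#' @return A ggplot object.
#' @export
plot_masked_depth <- function(stats) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$masked_fraction,
                                      y = .data$depth_hq)) +
    ggplot2::geom_point(ggplot2::aes(size = log10(.data$length),
                                     colour = .data$unique_kmer_fraction),
                        alpha = 0.8) +
    ggplot2::labs(x = "masked fraction", y = "median depth (MAPQ stratum)",
                  colour = "unique k-mer fraction", size = "log10 length")
}

#' Phase blocks vs heterozygous sites plot
#'
#' @param summary A [phase_block_summary()] result.
#' @param contig_lengths Optional named contig lengths (point size).
#' @return A ggplot object.
#' @export
plot_phase_blocks <- function(summary, contig_lengths = NULL) {
  tbl <- filter(summary$per_contig, .data$n_het_sites > 0)
  if (!is.null(contig_lengths)) {
    tbl <- mutate(tbl, length = unname(contig_lengths[.data$contig]))
  }
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n_het_sites,
                                         y = .data$n_phase_blocks))
  p <- if (!is.null(contig_lengths)) {
    p + ggplot2::geom_point(ggplot2::aes(size = log10(.data$length)),
                            alpha = 0.8) +
      ggplot2::labs(size = "log10 length")
  } else {
    p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::scale_x_log10() +
    ggplot2::labs(x = "heterozygous sites", y = "phase blocks")
}

#' Upset-style bar chart of BUSCO intersection cardinalities
#'
#' Shows the top intersection patterns from [upset_intersections()] as a
#' ranked bar chart (the bar component of an upset plot).
#'
#' @param upset Tibble from [upset_intersections()].
#' @param max_patterns Patterns to show (default 15).
#' @return A ggplot object.
#' @export
plot_busco_upset <- function(upset, max_patterns = 15) {
  dat <- head(upset, max_patterns) |>
    mutate(rank = factor(seq_len(n())))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$n_busco)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_species), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "intersection rank (label = species in pattern)",
                  y = "BUSCOs in intersection")
}
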