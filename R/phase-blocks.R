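#' Summarize phasing structure from a phased call set
#'
#' Counts phase blocks per contig as the number of distinct PS (phase set)
#' values among phased heterozygous records, and reports the fraction of
#' contigs phased into a single block and into three or fewer. Contigs with
#' heterozygous records but no PS tag at all are counted unphased and
#' excluded from the fractions by default; the denominator policy is
#' recorded in the output.
#'
#' @param records Variant tibble from a phased VCF (needs `genotype` and
#'   `phase_set`).
#' @param denominator `"phased"` (contigs with >= 1 phased het record;
#'   default) or `"all"` (every contig in `contig_lengths`).
#' @param contig_lengths Named lengths; required for the `"all"` policy and
#'   used to report zero rows for variant-free contigs.
#' @return A `phase_summary`: list with `per_contig` tibble (`contig`,
#'   `n_het_sites`, `n_phased`, `n_phase_blocks`, `largest_block_span`) and
#'   one-row `global` tibble.
#' @export
phase_block_summary <- function(records, denominator = c("phased", "all"),
                                contig_lengths = NULL) {
  denominator <- match.arg(denominator)
  het <- filter(records,
                .data$genotype %in% c("0/1", "0|1", "1|0", "1/0"))
  if (nrow(het) > 0 && all(is.na(het$phase_set))) {
    abort("no PS tags found on heterozygous records; is the input phased?")
  }
  per_contig <- het |>
    group_by(contig = .data$contig) |>
    summarise(
      n_het_sites = n(),
      n_phased = sum(!is.na(.data$phase_set)),
      n_phase_blocks = n_distinct(.data$phase_set[!is.na(.data$phase_set)]),
      largest_block_span = {
        ph <- filter(pick(everything()), !is.na(.data$phase_set))
        if (nrow(ph) == 0) NA_real_ else
          max(tapply(ph$pos, ph$phase_set,
                     function(p) diff(range(p)) + 1))
      },
      .groups = "drop"
    )
  if (!is.null(contig_lengths)) {
    per_contig <- tibble(contig = names(contig_lengths)) |>
      left_join(per_contig, by = "contig") |>
      mutate(across(c("n_het_sites", "n_phased", "n_phase_blocks"),
                    ~ coalesce(.x, 0L)))
  }
  eligible <- filter(per_contig, .data$n_phased > 0)
  denom <- if (denominator == "phased") nrow(eligible) else nrow(per_contig)
  global <- tibble(
    n_contigs = nrow(per_contig),
    n_contigs_phased = nrow(eligible),
    denominator_policy = denominator,
    frac_single_block = if (denom > 0)
      sum(eligible$n_phase_blocks == 1) / denom else NA_real_,
    frac_le3_blocks = if (denom > 0)
      sum(eligible$n_phase_blocks <= 3 & eligible$n_phase_blocks >= 1) / denom
      else NA_real_
  )
  structure(list(per_contig = per_contig, global = global),
            class = "phase_summary")
}

#' @export
print.phase_summary <- function(x, ...) {
  cat("<phase_summary>\n")
  print(x$global)
  invisible(x)
}

#' @rdname phase_block_summary
#' @param x A `phase_summary`.
#' @param ... Unused.
#' @export
tidy.phase_summary <- function(x, ...) x$per_contig

#' @rdname phase_block_summary
#' @export
glance.phase_summary <- function(x, ...) x$global

#' Joint table of phase blocks vs heterozygosity
#'
#' Emits (contig length, het sites, blocks) rows for plotting or
#' regression; zero-het contigs are excluded (and reported via a message).
#' Contig class labels are joined in when provided.
#'
#' @param summary A [phase_block_summary()] result.
#' @param contig_lengths Named contig lengths.
#' @param labels Optional label tibble from [classify_contigs()].
#' @return Tibble with one row per contig with heterozygous sites.
#' @export
blocks_vs_heterozygosity <- function(summary, contig_lengths = NULL,
                                     labels = NULL) {
  tbl <- summary$per_contig
  dropped <- sum(tbl$n_het_sites == 0)
  if (dropped > 0) {
    inform(sprintf("excluding %d contig(s) with no heterozygous sites",
                   dropped))
  }
  tbl <- filter(tbl, .data$n_het_sites > 0)
  if (!is.null(contig_lengths)) {
    tbl <- mutate(tbl, length = unname(contig_lengths[.data$contig]),
                  .after = "contig")
  }
  if (!is.null(labels)) {
    tbl <- left_join(tbl, select(labels, contig = "contig_id", "label"),
                     by = "contig")
  }
  tbl
}
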