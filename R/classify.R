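#' Threshold configuration for contig triage
#'
#' Central home for every cutoff used by [classify_contigs()] and
#' [contaminant_screen()]. Depth cutoffs are *relative* to the estimated
#' primary (autosomal) depth mode so the same rules work at any coverage;
#' the defaults reproduce the absolute cutoffs "median depth < 30" and
#' "> 45-fold" at an autosomal mode of 52.
#'
#' @param k K-mer length for uniqueness (default 21).
#' @param mapq_min High-quality depth stratum cutoff, strict (default 20).
#' @param unique_kmer_min Contigs below this unique-k-mer fraction are
#'   collapsed repeats (default 0.90).
#' @param telomere_fold_min Telomere enrichment flag threshold (default 4).
#' @param sex_depth_max_rel Sex-candidate depth ceiling as a fraction of the
#'   primary mode (default 30/52).
#' @param autosome_depth_min_rel Autosomal depth floor as a fraction of the
#'   primary mode (default 45/52).
#' @param sketch_size MinHash sketch size (default 500000; scale down for
#'   small inputs).
#' @param minhash_k K-mer length for sketching (default 21).
#' @param small_contig_bp Contigs shorter than this fall back from mash
#'   distance to the longest-aligned-region rule (default 10000).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(k = 21L, mapq_min = 20L, unique_kmer_min = 0.90,
                             telomere_fold_min = 4.0,
                             sex_depth_max_rel = 30 / 52,
                             autosome_depth_min_rel = 45 / 52,
                             sketch_size = 500000L, minhash_k = 21L,
                             small_contig_bp = 10000L) {
  if (!(sex_depth_max_rel > 0 && sex_depth_max_rel < autosome_depth_min_rel &&
          autosome_depth_min_rel <= 1)) {
    abort("need 0 < sex_depth_max_rel < autosome_depth_min_rel <= 1")
  }
  if (sketch_size < 1) abort("sketch_size must be >= 1")
  structure(list(k = as.integer(k), mapq_min = as.integer(mapq_min),
                 unique_kmer_min = unique_kmer_min,
                 telomere_fold_min = telomere_fold_min,
                 sex_depth_max_rel = sex_depth_max_rel,
                 autosome_depth_min_rel = autosome_depth_min_rel,
                 sketch_size = as.integer(sketch_size),
                 minhash_k = as.integer(minhash_k),
                 small_contig_bp = as.integer(small_contig_bp)),
            class = "threshold_config")
}

#' Classify contigs from their diagnostic statistics
#'
#' Applies the triage rules in fixed order: (1) a contig with unique-k-mer
#' fraction below `unique_kmer_min` is a `collapsed_repeat` (low-complexity
#' contigs have unreliable high-MAPQ depth, so this rule outranks the depth
#' rules); (2) a nonrepetitive contig with high-quality depth below
#' `sex_depth_max_rel` times the primary mode is a `sex_candidate`; (3) one
#' above `autosome_depth_min_rel` times the primary mode is `autosomal`;
#' (4) anything else is `unresolved`. Telomere enrichment at or above
#' `telomere_fold_min` sets an independent `telomere_flag`.
#'
#' @param stats Per-contig statistics from [contig_stats()].
#' @param config A [threshold_config()].
#' @param modes Optional precomputed [estimate_depth_modes()] result;
#'   estimated from `stats` (length-weighted) when `NULL`.
#' @return Tibble: `contig_id`, `length`, `label`, `telomere_flag`,
#'   `evidence`, plus the depth and uniqueness values the rules used.
#' @export
classify_contigs <- function(stats, config = threshold_config(),
                             modes = NULL) {
  modes <- modes %||% estimate_depth_modes(stats$depth_hq,
                                           weights = stats$length)
  sex_max <- config$sex_depth_max_rel * modes$primary
  auto_min <- config$autosome_depth_min_rel * modes$primary

  stats |>
    mutate(
      label = case_when(
        .data$unique_kmer_fraction < config$unique_kmer_min ~ "collapsed_repeat",
        .data$depth_hq < sex_max ~ "sex_candidate",
        .data$depth_hq > auto_min ~ "autosomal",
        TRUE ~ "unresolved"
      ),
      telomere_flag = .data$telomere_enrichment >= config$telomere_fold_min,
      evidence = case_when(
        .data$label == "collapsed_repeat" ~ sprintf(
          "unique_kmer_fraction=%.3f < %.2f", .data$unique_kmer_fraction,
          config$unique_kmer_min),
        .data$label == "sex_candidate" ~ sprintf(
          "depth_hq=%.1f < %.1f (%.3f x mode %.0f)", .data$depth_hq, sex_max,
          config$sex_depth_max_rel, modes$primary),
        .data$label == "autosomal" ~ sprintf(
          "depth_hq=%.1f > %.1f (%.3f x mode %.0f)", .data$depth_hq, auto_min,
          config$autosome_depth_min_rel, modes$primary),
        TRUE ~ NA_character_
      )
    ) |>
    select("contig_id", "length", "label", "telomere_flag", "evidence",
           "depth_all", "depth_hq", "unique_kmer_fraction",
           "telomere_enrichment")
}
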