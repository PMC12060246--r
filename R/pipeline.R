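#' Run the diagnostic pipeline end to end
#'
#' Executes the enabled stages in dependency order — synthesize, stats,
#' classify, variants, phase, busco — writing each stage's tables under
#' `outdir` together with a manifest (parameters plus input checksums).
#' A stage whose manifest matches the previous run is skipped and its
#' cached outputs reused. With a `spec`, stage inputs come from the
#' synthetic generator; alternatively `inputs` can point at external
#' FASTA/SAM/VCF/GFF3/BUSCO files.
#'
#' @param outdir Output directory (created if needed).
#' @param spec A [synth_spec()] driving the synthesize stage, or `NULL`
#'   when all inputs are external.
#' @param config A [threshold_config()].
#' @param stages Character vector of stages to run.
#' @param inputs Named list of external input paths (`fasta`, `sam`,
#'   `vcf_a`, `vcf_b`, `gff`, `busco_status`) used where the synthesize
#'   stage is disabled.
#' @param genome_size_assumed Assumed genome size for NG50 (`NULL` to
#'   default to the assembly span).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of stage result objects plus the rendered
#'   report path.
#' @export
run_pipeline <- function(outdir, spec = synth_spec(),
                         config = threshold_config(),
                         stages = c("synthesize", "stats", "classify",
                                    "variants", "phase", "busco"),
                         inputs = list(), genome_size_assumed = NULL,
                         quiet = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  path <- function(...) file.path(outdir, ...)
  results <- list()

  stage_cached <- function(stage, params, input_files, output_files) {
    mf <- path(sprintf("manifest_%s.json", stage))
    input_files <- input_files[file.exists(input_files)]
    current <- list(
      stage = stage, params = params,
      inputs = as.list(tools::md5sum(input_files))
    )
    cached <- file.exists(mf) && all(file.exists(path(output_files))) &&
      identical(jsonlite::fromJSON(mf),
                jsonlite::fromJSON(jsonlite::toJSON(current, auto_unbox = TRUE,
                                                    digits = NA)))
    if (!cached) {
      jsonlite::write_json(current, mf, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    cached
  }

  need <- function(file, stage) {
    p <- path(file)
    if (!file.exists(p)) {
      abort(sprintf("stage '%s': missing upstream output '%s'", stage, file))
    }
    p
  }
  resolve <- function(input_name, file, stage) {
    if (!is.null(inputs[[input_name]])) inputs[[input_name]]
    else need(file, stage)
  }

  ## ------------------------------------------------------------ synthesize
  if ("synthesize" %in% stages) {
    outs <- c("assembly.fasta", "truth_contigs.tsv", "alignments.sam",
              "annotation.gff3", "caller_a.vcf", "caller_b.vcf",
              "variant_truth.tsv", "phase_truth.tsv", "dips.tsv",
              "busco_status.tsv", "busco_truth.tsv",
              "ref_expected.fasta", "ref_contaminant.fasta")
    params <- spec[setdiff(names(spec), "length_range")]
    params$length_range <- unlist(spec$length_range)
    if (!stage_cached("synthesize", params, character(0), outs)) {
      say("synthesize", "generating genome, reads, annotation, call sets")
      gen <- generate_assembly(spec)
      write_fasta(gen$assembly, path("assembly.fasta"))
      readr::write_tsv(gen$truth, path("truth_contigs.tsv"))
      if (!is.null(gen$references$expected)) {
        write_fasta(c(expected = gen$references$expected),
                    path("ref_expected.fasta"))
      }
      if (!is.null(gen$references$contaminant)) {
        write_fasta(c(contaminant = gen$references$contaminant),
                    path("ref_contaminant.fasta"))
      }
      aln <- simulate_alignments(gen$assembly, gen$truth,
                                 seed = spec$seed + 1L,
                                 mapq0_prob = spec$collapsed_mapq0_prob)
      write_sam(aln, setNames(gen$truth$length, gen$truth$contig_id),
                path("alignments.sam"))
      ann <- generate_annotation(gen$assembly, seed = spec$seed + 2L)
      write_gff3(ann, path("annotation.gff3"))
      calls <- simulate_callsets(gen$assembly, ann, gen$truth,
                                 seed = spec$seed + 3L)
      lens <- setNames(gen$truth$length, gen$truth$contig_id)
      write_vcf(select(calls$a, -"phase_set"), lens, path("caller_a.vcf"),
                sample_name = "caller_a")
      write_vcf(calls$b, lens, path("caller_b.vcf"), sample_name = "caller_b")
      readr::write_tsv(calls$variant_truth, path("variant_truth.tsv"))
      readr::write_tsv(calls$phase_truth, path("phase_truth.tsv"))
      readr::write_tsv(calls$dips, path("dips.tsv"))
      busco <- generate_busco_fixture(seed = spec$seed + 4L)
      readr::write_tsv(busco$status_map, path("busco_status.tsv"))
      readr::write_tsv(busco$truth, path("busco_truth.tsv"))
    } else {
      say("synthesize", "cache hit, reusing outputs")
    }
    results$synthesize <- "done"
  }

  ## ------------------------------------------------------------------ stats
  if ("stats" %in% stages) {
    fasta <- resolve("fasta", "assembly.fasta", "stats")
    sam <- resolve("sam", "alignments.sam", "stats")
    outs <- c("contig_stats.tsv", "assembly_metrics.json")
    params <- list(k = config$k, mapq_min = config$mapq_min,
                   genome_size_assumed = genome_size_assumed)
    if (!stage_cached("stats", params, c(fasta, sam), outs)) {
      say("stats", "computing per-contig statistics")
      seqs <- read_fasta(fasta)
      aln <- read_sam(sam)
      stats <- contig_stats(seqs, aln, k = config$k,
                            mapq_min = config$mapq_min)
      readr::write_tsv(stats, path("contig_stats.tsv"))
      metrics <- assembly_metrics(
        stats$length,
        genome_size_assumed = genome_size_assumed %||% sum(stats$length))
      jsonlite::write_json(as.list(metrics), path("assembly_metrics.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      say("stats", "cache hit, reusing outputs")
    }
    results$stats <- readr::read_tsv(path("contig_stats.tsv"),
                                     show_col_types = FALSE)
  }

  ## --------------------------------------------------------------- classify
  if ("classify" %in% stages) {
    stats_path <- need("contig_stats.tsv", "classify")
    fasta <- resolve("fasta", "assembly.fasta", "classify")
    outs <- "contig_labels.tsv"
    params <- unclass(config)
    if (!stage_cached("classify", params, c(stats_path, fasta), outs)) {
      say("classify", "estimating depth modes and labelling contigs")
      stats <- readr::read_tsv(stats_path, show_col_types = FALSE)
      labels <- classify_contigs(stats, config)
      ref_e <- path("ref_expected.fasta")
      ref_c <- path("ref_contaminant.fasta")
      if (file.exists(ref_e) && file.exists(ref_c)) {
        seqs <- read_fasta(fasta)
        sk_e <- minhash_sketch(read_fasta(ref_e)[[1]], config$minhash_k,
                               config$sketch_size)
        sk_c <- minhash_sketch(read_fasta(ref_c)[[1]], config$minhash_k,
                               config$sketch_size)
        screen <- contaminant_screen(seqs, sk_e, sk_c, config = config)
        labels <- labels |>
          left_join(select(screen, "contig_id", "assignment"),
                    by = "contig_id") |>
          mutate(label = if_else(.data$assignment == "contaminant_candidate",
                                 "contaminant_candidate", .data$label))
      }
      readr::write_tsv(labels, path("contig_labels.tsv"))
    } else {
      say("classify", "cache hit, reusing outputs")
    }
    results$classify <- readr::read_tsv(path("contig_labels.tsv"),
                                        show_col_types = FALSE)
  }

  ## --------------------------------------------------------------- variants
  if ("variants" %in% stages) {
    fasta <- resolve("fasta", "assembly.fasta", "variants")
    vcf_a <- resolve("vcf_a", "caller_a.vcf", "variants")
    vcf_b <- resolve("vcf_b", "caller_b.vcf", "variants")
    gff <- resolve("gff", "annotation.gff3", "variants")
    labels_path <- need("contig_labels.tsv", "variants")
    outs <- c("highconf.vcf", "intersection_counts.tsv", "partition.tsv",
              "frame_spectrum.tsv", "density_by_class.tsv",
              "quality_thresholds.tsv")
    params <- list()
    if (!stage_cached("variants", params,
                      c(fasta, vcf_a, vcf_b, gff, labels_path), outs)) {
      say("variants", "dual-caller consensus and genic partitioning")
      seqs <- read_fasta(fasta)
      lens <- setNames(nchar(seqs), names(seqs))
      a <- normalize_variants(read_vcf(vcf_a), seqs)
      b <- normalize_variants(read_vcf(vcf_b), seqs)
      dip_a <- detect_quality_dip(a$qual)
      dip_b <- detect_quality_dip(b$qual)
      readr::write_tsv(tibble(caller = c("a", "b"),
                              threshold = c(dip_a, dip_b)),
                       path("quality_thresholds.tsv"))
      isec <- intersect_callsets(filter_by_quality(a, dip_a),
                                 filter_by_quality(b, dip_b))
      readr::write_tsv(isec$counts, path("intersection_counts.tsv"))
      write_vcf(mutate(isec$shared, genotype = coalesce(.data$genotype, "0/1")),
                lens, path("highconf.vcf"), sample_name = "consensus")
      ann <- read_gff3(gff)
      index <- build_annotation_index(ann, lens)
      summ <- annotation_summary(index, sum(lens))
      part <- partition_by_annotation(isec$shared, index, summ)
      readr::write_tsv(left_join(part$by_region,
                                 select(part$depletion, "class",
                                        "depletion_fold"),
                                 by = "class"),
                       path("partition.tsv"))
      readr::write_tsv(indel_frame_spectrum(isec$shared, index),
                       path("frame_spectrum.tsv"))
      labels <- readr::read_tsv(labels_path, show_col_types = FALSE)
      dens <- density_by_contig_class(isec$shared, labels)
      readr::write_tsv(dens$per_class, path("density_by_class.tsv"))
    } else {
      say("variants", "cache hit, reusing outputs")
    }
    results$variants <- readr::read_tsv(path("density_by_class.tsv"),
                                        show_col_types = FALSE)
  }

  ## ------------------------------------------------------------------ phase
  if ("phase" %in% stages) {
    vcf_b <- resolve("vcf_b", "caller_b.vcf", "phase")
    outs <- c("phase_per_contig.tsv", "phase_global.json")
    if (!stage_cached("phase", list(), vcf_b, outs)) {
      say("phase", "summarizing phase blocks")
      ps <- phase_block_summary(read_vcf(vcf_b))
      readr::write_tsv(ps$per_contig, path("phase_per_contig.tsv"))
      jsonlite::write_json(as.list(ps$global), path("phase_global.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      say("phase", "cache hit, reusing outputs")
    }
    results$phase <- readr::read_tsv(path("phase_per_contig.tsv"),
                                     show_col_types = FALSE)
  }

  ## ------------------------------------------------------------------ busco
  if ("busco" %in% stages) {
    status_path <- resolve("busco_status", "busco_status.tsv", "busco")
    outs <- c("busco_percentages.tsv", "busco_upset_single.tsv",
              "busco_upset_missing.tsv", "busco_adjusted.json")
    if (!stage_cached("busco", list(), status_path, outs)) {
      say("busco", "comparative completeness analysis")
      status_map <- readr::read_tsv(status_path, show_col_types = FALSE)
      counts <- status_map |>
        count(.data$species, .data$status) |>
        tidyr::pivot_wider(names_from = "status", values_from = "n",
                           values_fill = 0L)
      for (col in c("single", "duplicated", "missing", "fragmented")) {
        if (!col %in% names(counts)) counts[[col]] <- 0L
      }
      pct <- completeness_percentages(counts)
      readr::write_tsv(pct, path("busco_percentages.tsv"))
      up_s <- upset_intersections(status_map, "single", top_n = 15)
      up_m <- upset_intersections(status_map, "missing", top_n = 15)
      readr::write_tsv(up_s, path("busco_upset_single.tsv"))
      readr::write_tsv(up_m, path("busco_upset_missing.tsv"))
      n_sp <- dplyr::n_distinct(status_map$species)
      missing_in_all <- up_m |>
        filter(.data$n_species == n_sp) |>
        pull(.data$n_busco)
      missing_in_all <- if (length(missing_in_all)) missing_in_all[1] else 0L
      adj <- ancestral_missing_adjustment(counts, missing_in_all)
      jsonlite::write_json(
        list(missing_in_all = missing_in_all,
             adjusted_mean_missing = adj$adjusted_mean_missing,
             adjusted_total = adj$per_species$adjusted_total[1]),
        path("busco_adjusted.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    } else {
      say("busco", "cache hit, reusing outputs")
    }
    results$busco <- readr::read_tsv(path("busco_percentages.tsv"),
                                     show_col_types = FALSE)
  }

  report <- render_report(outdir)
  results$report <- report
  invisible(results)
}

#' Render a consolidated markdown report from stage outputs
#'
#' Collects whatever stage tables exist under `outdir` into one
#' human-readable markdown report: a per-contig diagnostics table (GC,
#' depth at both strata, unique-k-mer and masked fractions), label counts,
#' SNP-density and phase-block tables, and the BUSCO percentage table.
#' Stages without outputs are marked "not run".
#'
#' @param outdir Pipeline output directory.
#' @return Path to the written `report.md`, invisibly.
#' @export
render_report <- function(outdir) {
  path <- function(...) file.path(outdir, ...)
  md <- c("# Assembly diagnostics report", "")
  tsv_or_null <- function(f) {
    p <- path(f)
    if (file.exists(p)) readr::read_tsv(p, show_col_types = FALSE) else NULL
  }
  md_table <- function(tbl, digits = 3) {
    tbl <- mutate(tbl, across(everything(),
                              ~ if (is.numeric(.x)) round(.x, digits) else .x))
    header <- paste("|", paste(names(tbl), collapse = " | "), "|")
    sep <- paste("|", paste(rep("---", ncol(tbl)), collapse = " | "), "|")
    rows <- apply(tbl, 1, function(r) paste("|", paste(r, collapse = " | "),
                                            "|"))
    c(header, sep, rows)
  }
  section <- function(title, tbl, max_rows = 30) {
    if (is.null(tbl)) {
      c(sprintf("## %s", title), "", "not run", "")
    } else {
      c(sprintf("## %s", title), "", md_table(head(tbl, max_rows)), "")
    }
  }
  md <- c(md,
          section("Per-contig statistics", tsv_or_null("contig_stats.tsv")),
          section("Contig labels",
                  {
                    lab <- tsv_or_null("contig_labels.tsv")
                    if (is.null(lab)) NULL else count(lab, .data$label)
                  }),
          section("Variant quality thresholds",
                  tsv_or_null("quality_thresholds.tsv")),
          section("Call-set intersection",
                  tsv_or_null("intersection_counts.tsv")),
          section("Genic partition", tsv_or_null("partition.tsv")),
          section("Indel frame spectrum", tsv_or_null("frame_spectrum.tsv")),
          section("SNP density by contig class",
                  tsv_or_null("density_by_class.tsv")),
          section("Phase blocks per contig",
                  tsv_or_null("phase_per_contig.tsv")),
          section("BUSCO completeness", tsv_or_null("busco_percentages.tsv")),
          section("BUSCO upset (single-copy)",
                  tsv_or_null("busco_upset_single.tsv")))
  writeLines(md, path("report.md"))
  invisible(path("report.md"))
}
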