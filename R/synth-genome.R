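#' Generate a synthetic assembly with known per-contig truth
#'
#' Emits one contig per truth row. Autosomal and sex contigs are random
#' DNA at their class GC; collapsed contigs are a short tandem-repeat unit
#' repeated to length (soft-masked lowercase, emulating a repeat-masked
#' input) capped with a telomere-motif array, which guarantees a unique
#' 21-mer fraction far below 0.5; contaminant contigs come from a separate
#' composition model (distinct GC, distinct k-mer source). Two synthetic
#' reference genomes are also returned for the contaminant screen: an
#' "expected" reference diverged from the host contigs by `spec$divergence`
#' substitutions/bp, and a "contaminant" reference diverged likewise from
#' the contaminant source.
#'
#' @param spec A [synth_spec()].
#' @return List: `assembly` (named character vector), `truth` (per-contig
#'   tibble: `contig_id`, `class`, `length`, `gc_target`, `target_depth`,
#'   `het_snv_rate`, `het_indel_rate`), and `references` (list `expected`,
#'   `contaminant`; `NULL` when the class is absent).
#' @export
generate_assembly <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  classes <- rep(c("autosomal", "sex", "collapsed", "contaminant"),
                 times = c(spec$n_autosomal, spec$n_sex, spec$n_collapsed,
                           spec$n_contaminant))
  n <- length(classes)
  if (n == 0) {
    return(list(assembly = setNames(character(0), character(0)),
                truth = tibble(contig_id = character(), class = character(),
                               length = integer(), gc_target = numeric(),
                               target_depth = numeric(),
                               het_snv_rate = numeric(),
                               het_indel_rate = numeric()),
                references = list(expected = NULL, contaminant = NULL)))
  }
  ids <- sprintf("contig_%03d", seq_len(n))
  depths <- c(autosomal = spec$autosomal_depth, sex = spec$sex_depth,
              collapsed = spec$collapsed_depth,
              contaminant = spec$contaminant_depth)
  local_seed(spec$seed, {
    lens <- vapply(classes, function(cl) {
      r <- spec$length_range[[cl]]
      as.integer(round(runif(1, r[1], r[2])))
    }, integer(1), USE.NAMES = FALSE)

    seqs <- character(n)
    for (i in seq_len(n)) {
      cl <- classes[i]
      gc <- spec$gc_target[[cl]]
      if (cl == "collapsed") {
        unit <- random_dna(spec$repeat_unit_len, gc)
        body_len <- lens[i] - spec$telomere_array_len
        body <- strtrim(strrep(unit, ceiling(body_len / nchar(unit))),
                        body_len)
        tel <- strtrim(strrep("TTAGGG",
                              ceiling(spec$telomere_array_len / 6)),
                       spec$telomere_array_len)
        seqs[i] <- paste0(tolower(body), tel)  # body soft-masked
      } else {
        seqs[i] <- random_dna(lens[i], gc)
      }
    }
    names(seqs) <- ids

    host <- classes %in% c("autosomal", "sex")
    expected_ref <- if (any(host)) {
      mutate_sequence(paste(toupper(seqs[host]), collapse = ""),
                      spec$divergence)
    } else NULL
    contaminant_ref <- if (any(classes == "contaminant")) {
      src <- paste(toupper(seqs[classes == "contaminant"]), collapse = "")
      # pad so the contaminant reference is genome-like, not contig-sized
      pad <- random_dna(max(0L, 200000L - nchar(src)),
                        spec$gc_target[["contaminant"]])
      mutate_sequence(paste0(src, pad), spec$divergence)
    } else NULL

    truth <- tibble(
      contig_id = ids, class = classes, length = lens,
      gc_target = unname(spec$gc_target[classes]),
      target_depth = unname(depths[classes]),
      het_snv_rate = unname(spec$het_snv_rate[classes]),
      het_indel_rate = unname(spec$het_indel_rate[classes])
    )
    list(assembly = seqs, truth = truth,
         references = list(expected = expected_ref,
                           contaminant = contaminant_ref))
  })
}
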