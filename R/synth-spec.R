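#' Specification for a synthetic diagnostic-test genome
#'
#' Describes the ground-truth structure the generator emulates: a male
#' diploid assembly with autosomal contigs at a ~52-fold depth mode and
#' sex-linked contigs at a ~26-fold mode, low-complexity collapsed contigs
#' built from short tandem repeats plus a telomere-motif array (unique
#' 21-mer fraction well under 0.5, very high all-read depth, almost no
#' high-MAPQ depth), and contaminant contigs drawn from a compositionally
#' distinct source genome. Heterozygous SNVs arise at ~2.4/kbp on autosomes
#' and ~0.12/kbp on sex contigs (a 20-fold contrast).
#'
#' @param n_autosomal,n_sex,n_collapsed,n_contaminant Contig counts per
#'   class.
#' @param length_range Named list of `c(min, max)` bp per class.
#' @param gc_target Named GC fractions per class.
#' @param het_snv_rate,het_indel_rate Named per-bp heterozygous event rates
#'   per class.
#' @param telomere_array_len Telomere-array bp appended to collapsed
#'   contigs.
#' @param repeat_unit_len Tandem repeat unit length for collapsed contigs.
#' @param autosomal_depth,sex_depth,collapsed_depth,contaminant_depth
#'   Target fold depths (sex must be below autosomal).
#' @param collapsed_mapq0_prob Probability a read from a collapsed contig
#'   maps with MAPQ 0 (ambiguous-placement proxy).
#' @param divergence Per-base substitution rate separating the synthetic
#'   reference genomes from the contigs sliced out of them.
#' @param seed Integer seed; identical spec + seed gives byte-identical
#'   outputs.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_autosomal = 12L, n_sex = 4L, n_collapsed = 3L,
                       n_contaminant = 1L,
                       length_range = list(autosomal = c(250e3, 350e3),
                                           sex = c(150e3, 250e3),
                                           collapsed = c(60e3, 120e3),
                                           contaminant = c(30e3, 60e3)),
                       gc_target = c(autosomal = 0.41, sex = 0.40,
                                     collapsed = 0.44, contaminant = 0.55),
                       het_snv_rate = c(autosomal = 0.0024, sex = 0.00012,
                                        collapsed = 0, contaminant = 0),
                       het_indel_rate = c(autosomal = 5e-4, sex = 2.5e-5,
                                          collapsed = 0, contaminant = 0),
                       telomere_array_len = 5000L,
                       repeat_unit_len = 50L,
                       autosomal_depth = 52, sex_depth = 26,
                       collapsed_depth = 150, contaminant_depth = 52,
                       collapsed_mapq0_prob = 0.95,
                       divergence = 0.02,
                       seed = 1L) {
  counts <- c(n_autosomal = n_autosomal, n_sex = n_sex,
              n_collapsed = n_collapsed, n_contaminant = n_contaminant)
  bad <- names(counts)[counts < 0]
  if (length(bad)) abort(sprintf("negative count field(s): %s",
                                 paste(bad, collapse = ", ")))
  bad_gc <- names(gc_target)[gc_target <= 0 | gc_target >= 1]
  if (length(bad_gc)) abort(sprintf("gc_target out of (0,1): %s",
                                    paste(bad_gc, collapse = ", ")))
  if (any(het_snv_rate < 0)) abort("het_snv_rate must be >= 0")
  if (any(het_indel_rate < 0)) abort("het_indel_rate must be >= 0")
  if (!sex_depth < autosomal_depth) abort("sex_depth must be < autosomal_depth")
  if (n_collapsed > 0 && length_range$collapsed[1] <= telomere_array_len) {
    abort("collapsed length_range must exceed telomere_array_len")
  }
  structure(list(
    n_autosomal = as.integer(n_autosomal), n_sex = as.integer(n_sex),
    n_collapsed = as.integer(n_collapsed),
    n_contaminant = as.integer(n_contaminant),
    length_range = length_range, gc_target = gc_target,
    het_snv_rate = het_snv_rate, het_indel_rate = het_indel_rate,
    telomere_array_len = as.integer(telomere_array_len),
    repeat_unit_len = as.integer(repeat_unit_len),
    autosomal_depth = autosomal_depth, sex_depth = sex_depth,
    collapsed_depth = collapsed_depth,
    contaminant_depth = contaminant_depth,
    collapsed_mapq0_prob = collapsed_mapq0_prob,
    divergence = divergence,
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat("<synth_spec>", x$n_autosomal, "autosomal /", x$n_sex, "sex /",
      x$n_collapsed, "collapsed /", x$n_contaminant,
      "contaminant contigs; seed", x$seed, "\n")
  invisible(x)
}
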