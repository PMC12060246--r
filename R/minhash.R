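#' MinHash sketch of a sequence
#'
#' Hashes every canonical k-mer with a fixed 64-bit mix (splitmix64 finalizer,
#' truncated to 53 bits so values are exact doubles) and keeps the
#' `sketch_size` smallest distinct values. Sketches are reproducible across
#' runs and platforms. When the sequence has fewer distinct k-mers than
#' `sketch_size` the sketch is the full hash set.
#'
#' @param sequence A single DNA string, length >= `k`.
#' @param k K-mer length (default 21).
#' @param sketch_size Number of hashes to keep (default 500000, the value
#'   used for reference-scale screening; use far less for small inputs).
#' @return A `minhash_sketch` object: list with `k`, `sketch_size`, and the
#'   ascending `hashes`.
#' @export
minhash_sketch <- function(sequence, k = 21L, sketch_size = 500000L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < k) abort("sequence shorter than k")
  h <- .minhash_hashes_cpp(sequence, as.integer(k), as.integer(sketch_size))
  structure(list(k = as.integer(k), sketch_size = as.integer(sketch_size),
                 hashes = h),
            class = "minhash_sketch")
}

#' @export
print.minhash_sketch <- function(x, ...) {
  cat("<minhash_sketch> k:", x$k, " size:", length(x$hashes), "/",
      x$sketch_size, "\n")
  invisible(x)
}

# Bottom-sketch Jaccard estimate: take the s smallest hashes of the merged
# sketch and count how many occur in both sketches. Exact Jaccard when both
# sketches are saturated (hold their full k-mer hash sets).
estimate_jaccard <- function(a, b) {
  if (a$k != b$k) abort("sketch k mismatch")
  u <- sort(unique(c(a$hashes, b$hashes)))
  s <- min(min(a$sketch_size, b$sketch_size), length(u))
  if (s == 0) return(0)
  su <- u[seq_len(s)]
  shared <- sum(su %in% a$hashes & su %in% b$hashes)
  shared / s
}

#' Mash distance between two MinHash sketches
#'
#' Estimates the k-mer-set Jaccard index `j` with the bottom-sketch
#' estimator, then converts it to the Mash evolutionary-distance-like score
#' `d = -(1/k) * ln(2j / (1 + j))`; `d = 0` when `j = 1` and `d` is capped
#' at 1 when `j = 0`.
#'
#' @param a,b `minhash_sketch` objects with the same `k`.
#' @return Distance in \[0, 1\].
#' @examples
#' # closed form at j = 0.5, k = 21: -log(2/3)/21
#' @export
mash_distance <- function(a, b) {
  if (a$k != b$k) abort("sketch k mismatch")
  mash_dist_from_jaccard(estimate_jaccard(a, b), a$k)
}

#' Mash distance from a Jaccard index
#'
#' The closed-form transform underlying [mash_distance()]:
#' `d = -(1/k) * ln(2j / (1 + j))`, with `d = 0` at `j = 1` and a cap of 1
#' at `j = 0`. Exposed separately so the transform can be evaluated at
#' chosen Jaccard values.
#'
#' @param j Jaccard index in \[0, 1\].
#' @param k K-mer length the Jaccard was computed over.
#' @return Distance in \[0, 1\].
#' @examples
#' mash_dist_from_jaccard(0.5, 21) # -log(2/3)/21
#' @export
mash_dist_from_jaccard <- function(j, k) {
  stopifnot(j >= 0, j <= 1, k >= 1)
  if (j == 0) return(1.0)
  if (j == 1) return(0.0)
  min(1.0, -(1 / k) * log(2 * j / (1 + j)))
}

#' Screen contigs against an expected and a contaminant reference
#'
#' Each contig is assigned to whichever reference it is closer to by mash
#' distance. Contigs shorter than `config$small_contig_bp` -- or whose
#' sketch shares no hashes with either reference -- are too small for a
#' reliable distance and fall back to comparing the single longest aligned
#' block (PAF alignment block length, column 11) against each reference;
#' ties, or a fallback with no alignments, leave the contig `unresolved`.
#'
#' @param contigs Named character vector of contig sequences.
#' @param ref_expected,ref_contaminant [minhash_sketch()]es of the expected
#'   (conspecific) and suspected-contaminant reference genomes.
#' @param alignments Optional PAF tibble (see [read_paf()]) of contig
#'   alignments to both references.
#' @param config A [threshold_config()]; supplies `minhash_k`,
#'   `sketch_size`, `small_contig_bp`.
#' @param expected_targets,contaminant_targets PAF `target` names belonging
#'   to each reference.
#' @param sum_blocks Use summed block length per reference instead of the
#'   single longest block (default `FALSE`).
#' @return Tibble: `contig_id`, `assignment` (`expected`,
#'   `contaminant_candidate` or `unresolved`), `method` (`mash` or
#'   `alignment`), `dist_expected`, `dist_contaminant`, `block_expected`,
#'   `block_contaminant`.
#' @export
contaminant_screen <- function(contigs, ref_expected, ref_contaminant,
                               alignments = NULL,
                               config = threshold_config(),
                               expected_targets = "expected",
                               contaminant_targets = "contaminant",
                               sum_blocks = FALSE) {
  if (ref_expected$k != ref_contaminant$k) abort("reference sketch k mismatch")

  longest_block <- function(contig, targets) {
    if (is.null(alignments)) return(NA_real_)
    hits <- filter(alignments, .data$query == contig,
                   .data$target %in% targets)
    if (nrow(hits) == 0) return(NA_real_)
    if (sum_blocks) sum(hits$block_len) else max(hits$block_len)
  }

  rows <- imap(contigs, function(s, id) {
    len <- nchar(s)
    d_exp <- NA_real_
    d_con <- NA_real_
    use_mash <- len >= config$small_contig_bp && len >= config$minhash_k
    if (use_mash) {
      sk <- minhash_sketch(s, k = config$minhash_k,
                           sketch_size = config$sketch_size)
      j_exp <- estimate_jaccard(sk, ref_expected)
      j_con <- estimate_jaccard(sk, ref_contaminant)
      if (j_exp == 0 && j_con == 0) {
        use_mash <- FALSE  # sketch shares nothing with either reference
      } else {
        d_exp <- mash_distance(sk, ref_expected)
        d_con <- mash_distance(sk, ref_contaminant)
      }
    }
    if (use_mash) {
      assignment <- if (d_con < d_exp) "contaminant_candidate"
        else if (d_exp < d_con) "expected" else "unresolved"
      tibble(contig_id = id, assignment = assignment, method = "mash",
             dist_expected = d_exp, dist_contaminant = d_con,
             block_expected = NA_real_, block_contaminant = NA_real_)
    } else {
      b_exp <- longest_block(id, expected_targets)
      b_con <- longest_block(id, contaminant_targets)
      assignment <- if (is.na(b_exp) && is.na(b_con)) "unresolved"
        else if (is.na(b_con) || (!is.na(b_exp) && b_exp > b_con)) "expected"
        else if (is.na(b_exp) || b_con > b_exp) "contaminant_candidate"
        else "unresolved"
      tibble(contig_id = id, assignment = assignment, method = "alignment",
             dist_expected = d_exp, dist_contaminant = d_con,
             block_expected = b_exp, block_contaminant = b_con)
    }
  })
  list_rbind(rows)
}
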