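#' Normalize variant records against the assembly
#'
#' Re-implementation of the usual pre-intersection normalization: multiallelic
#' records are split into biallelic ones, shared prefix/suffix bases are
#' trimmed, and indels are left-aligned against the reference sequence (the
#' classic truncate-or-extend-left loop), so that equivalent representations
#' from different callers become identical records. Output is sorted by
#' (contig, pos, ref, alt); the operation is idempotent.
#'
#' @param records Variant tibble (see [read_vcf()]).
#' @param seqs Named character vector of reference (assembly) sequences.
#' @return Normalized, sorted variant tibble with refreshed `vtype`.
#' @export
normalize_variants <- function(records, seqs) {
  if (nrow(records) == 0) {
    return(arrange(records, .data$contig, .data$pos, .data$ref, .data$alt))
  }
  # split multiallelics
  records <- tidyr::separate_rows(records, "alt", sep = ",")

  norm_one <- function(contig, pos, ref, alt) {
    if (!contig %in% names(seqs)) {
      abort(sprintf("contig '%s' not in assembly", contig))
    }
    s <- seqs[[contig]]
    if (toupper(substr(s, pos, pos + nchar(ref) - 1L)) != toupper(ref)) {
      abort(sprintf("ref allele mismatch at %s:%d (VCF '%s' vs assembly '%s')",
                    contig, pos, ref,
                    substr(s, pos, pos + nchar(ref) - 1L)))
    }
    repeat {
      nr <- nchar(ref); na <- nchar(alt)
      if (nr > 0 && na > 0 &&
            toupper(substr(ref, nr, nr)) == toupper(substr(alt, na, na))) {
        ref <- substr(ref, 1L, nr - 1L)
        alt <- substr(alt, 1L, na - 1L)
        if (nchar(ref) == 0 || nchar(alt) == 0) {
          if (pos == 1L) {  # cannot extend past the contig start
            base <- toupper(substr(s, pos, pos))
            ref <- paste0(ref, base); alt <- paste0(alt, base)
            break
          }
          pos <- pos - 1L
          base <- toupper(substr(s, pos, pos))
          ref <- paste0(base, ref); alt <- paste0(base, alt)
        }
      } else break
    }
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
             toupper(substr(ref, 1L, 1L)) == toupper(substr(alt, 1L, 1L))) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    list(pos = pos, ref = toupper(ref), alt = toupper(alt))
  }

  out <- pmap(list(records$contig, records$pos, records$ref, records$alt),
              norm_one)
  records |>
    mutate(pos = map_int(out, ~ as.integer(.x$pos)),
           ref = map_chr(out, "ref"),
           alt = map_chr(out, "alt"),
           vtype = variant_type(.data$ref, .data$alt)) |>
    arrange(.data$contig, .data$pos, .data$ref, .data$alt)
}
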