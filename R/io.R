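#' Read a FASTA file preserving case
#'
#' Soft-masked (lowercase) bases are meaningful to [masked_fraction()], so
#' sequences are read as raw strings (via `Biostrings::readBStringSet`)
#' rather than through a DNA alphabet that would uppercase them.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (60-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Write alignment records to SAM
#'
#' Emits a valid SAM v1.6 file with `@SQ` header lines. Reads carry `*` in
#' the SEQ/QUAL columns: the diagnostics in this package consume only
#' placement (position, CIGAR span, MAPQ), so bases are never stored.
#'
#' @param alignments Tibble with columns `qname`, `flag`, `contig`, `pos`,
#'   `mapq`, `read_len`.
#' @param contig_lengths Named integer vector of contig lengths (the header).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, contig_lengths, path) {
  stopifnot(all(c("qname", "flag", "contig", "pos", "mapq", "read_len") %in%
                  names(alignments)))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
            as.integer(contig_lengths))
  )
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  alignments$qname, as.integer(alignments$flag),
                  alignments$contig, as.integer(alignments$pos),
                  as.integer(alignments$mapq), as.integer(alignments$read_len))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into an alignment tibble
#'
#' Converts through BAM with Rsamtools and reads alignments with
#' GenomicAlignments, so any spec-conformant SAM is accepted.
#'
#' @param path Path to a SAM file.
#' @return Tibble with columns `qname`, `flag`, `contig`, `pos`, `mapq`,
#'   `read_len` (reference span of the alignment).
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  gr <- GenomicRanges::granges(ga)
  si <- GenomeInfoDb::seqinfo(ga)
  out <- tibble(
    qname = S4Vectors::mcols(ga)$qname,
    flag = as.integer(S4Vectors::mcols(ga)$flag),
    contig = as.character(GenomicRanges::seqnames(gr)),
    pos = BiocGenerics::start(gr),
    mapq = as.integer(S4Vectors::mcols(ga)$mapq),
    read_len = BiocGenerics::width(gr)
  )
  attr(out, "contig_lengths") <- setNames(GenomeInfoDb::seqlengths(si),
                                          GenomeInfoDb::seqnames(si))
  out
}

#' Write variant records to VCF v4.2
#'
#' @param records Variant tibble with columns `contig`, `pos`, `ref`, `alt`,
#'   `qual`, `genotype` and optionally `phase_set`.
#' @param contig_lengths Named integer vector for `##contig` header lines.
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, contig_lengths, path, sample_name = "sample") {
  has_ps <- "phase_set" %in% names(records) && any(!is.na(records$phase_set))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
            as.integer(contig_lengths)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_ps)
      "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  fmt <- if (has_ps) "GT:PS" else "GT"
  sample_field <- if (has_ps) {
    ps <- ifelse(is.na(records$phase_set), ".",
                 as.character(records$phase_set))
    paste(records$genotype, ps, sep = ":")
  } else {
    records$genotype
  }
  body <- sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t.\t%s\t%s",
                  records$contig, as.integer(records$pos), records$ref,
                  records$alt, format(records$qual, trim = TRUE), fmt,
                  sample_field)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a variant tibble
#'
#' @param path Path to an uncompressed or gzipped VCF.
#' @return Tibble with columns `contig`, `pos`, `ref`, `alt`, `vtype`,
#'   `qual`, `genotype`, `phase_set`.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- tryCatch(as.vector(vcfR::extract.gt(v, element = "GT")),
                 error = function(e) rep(NA_character_, nrow(fix)))
  ps <- tryCatch(as.vector(vcfR::extract.gt(v, element = "PS")),
                 error = function(e) rep(NA_character_, nrow(fix)))
  tibble(
    contig = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    vtype = variant_type(fix$REF, fix$ALT),
    qual = as.numeric(fix$QUAL),
    genotype = gt,
    phase_set = suppressWarnings(as.integer(ps))
  )
}

#' Write gene annotation to GFF3
#'
#' @param annotation Annotation tibble with columns `contig`, `type`,
#'   `start`, `end`, `strand`, `feature_id`, `parent`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$contig,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$ID <- annotation$feature_id
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(annotation$parent), NA_character_,
                                        annotation$parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation into a tibble
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `contig`, `type`, `start`, `end`, `strand`,
#'   `feature_id`, `parent`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- S4Vectors::mcols(gr)$Parent
  parent_chr <- if (is.null(parent)) {
    rep(NA_character_, length(gr))
  } else if (methods::is(parent, "CharacterList")) {
    vapply(parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  } else {
    as.character(parent)
  }
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_id = as.character(S4Vectors::mcols(gr)$ID),
    parent = parent_chr
  )
}

#' Read a PAF alignment file
#'
#' Minimal reader for the 12 mandatory PAF columns (minimap2 output); SAM-style
#' tag columns beyond the twelfth are ignored. No installed R package parses
#' PAF, so this is a purpose-built reader.
#'
#' @param path Path to a PAF file.
#' @return Tibble with the 12 standard columns.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      query = character(), qlen = integer(), qstart = integer(),
      qend = integer(), strand = character(), target = character(),
      tlen = integer(), tstart = integer(), tend = integer(),
      n_match = integer(), block_len = integer(), mapq = integer()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad) > 0) {
    abort(sprintf("malformed PAF line %d: fewer than 12 fields", bad[1]))
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  num <- function(j) suppressWarnings(as.integer(m[, j]))
  out <- tibble(
    query = m[, 1], qlen = num(2), qstart = num(3), qend = num(4),
    strand = m[, 5], target = m[, 6], tlen = num(7), tstart = num(8),
    tend = num(9), n_match = num(10), block_len = num(11), mapq = num(12)
  )
  bad_num <- which(is.na(out$block_len))
  if (length(bad_num) > 0) {
    abort(sprintf("malformed PAF line %d: non-numeric block length",
                  bad_num[1]))
  }
  out
}
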