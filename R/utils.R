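#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement that preserves case and maps any
#' non-ACGT character to `N` (lowercase `n` for lowercase input).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("TTAGGG")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  flipped <- chartr("ACGTacgtNn", "TGCAtgcaNn", x)
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

# Random DNA of length n with a target GC fraction.
random_dna <- function(n, gc = 0.41) {
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run code under a fixed seed without disturbing the caller's RNG state.
local_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Substitute bases at a given per-base rate (used to diverge reference
# sequences from the contigs sliced out of them).
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- toupper(ch[p])
    if (cur %in% bases) ch[p] <- sample(setdiff(bases, cur), 1)
  }
  paste(ch, collapse = "")
}

# Classify a ref/alt pair. Multiallelic records (comma in alt) are "multi"
# until split by normalize_variants().
variant_type <- function(ref, alt) {
  dplyr::case_when(
    stringr::str_detect(alt, ",") ~ "multi",
    nchar(ref) == 1L & nchar(alt) == 1L ~ "snv",
    nchar(alt) > nchar(ref) ~ "ins",
    nchar(alt) < nchar(ref) ~ "del",
    TRUE ~ "mnp"
  )
}

# Centered moving average with shrinking windows at the edges.
smooth_counts <- function(x, window) {
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Indices of (weak) local maxima of a numeric vector.
local_maxima <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  left <- c(-Inf, x[-n])
  right <- c(x[-1], -Inf)
  which(x >= left & x > right | (x > left & x >= right))
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}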