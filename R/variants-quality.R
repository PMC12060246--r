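#' Detect the quality dip between error and true call modes
#'
#' Long-read caller quality distributions are typically bimodal: a
#' low-quality error mode and a high-quality true-call mode. This locates
#' the valley between them: integer-bin histogram, centered moving-average
#' smoothing (window 3), the two largest local maxima, and the bin of
#' minimum smoothed count strictly between them (leftmost on ties). A
#' unimodal histogram returns the configured fallback.
#'
#' @param qualities Numeric vector of call qualities (>= 100 values for a
#'   stable histogram; fewer triggers a warning).
#' @param fallback Threshold to return when no valley exists.
#' @param window Smoothing window (default 3).
#' @param min_separation Minimum distance in quality units between the two
#'   modes (default 10); peaks closer than this are treated as one mode.
#' @return Integer quality threshold (calls are then kept with
#'   `qual > threshold`, see [filter_by_quality()]).
#' @export
detect_quality_dip <- function(qualities, fallback = 14L, window = 3L,
                               min_separation = 10L) {
  if (length(qualities) == 0) abort("empty quality vector")
  if (length(qualities) < 100) {
    warn("fewer than 100 calls; dip detection may be unstable")
  }
  q <- round(qualities)
  bins <- min(q):max(q)
  counts <- vapply(bins, function(b) sum(q == b), numeric(1))
  sm <- smooth_counts(counts, window)
  peaks <- local_maxima(sm)
  peaks <- peaks[sm[peaks] > 0]
  if (length(peaks) < 2) return(as.integer(fallback))
  best <- peaks[which.max(sm[peaks])]
  far <- peaks[abs(peaks - best) >= min_separation]
  if (length(far) == 0) return(as.integer(fallback))
  second <- far[which.max(sm[far])]
  lo <- min(best, second); hi <- max(best, second)
  if (hi - lo < 2) return(as.integer(fallback))
  between <- (lo + 1L):(hi - 1L)
  valley <- between[which.min(sm[between])]  # which.min takes the leftmost tie
  as.integer(bins[valley])
}

#' Filter variant records by quality
#'
#' Keeps records with quality strictly above the threshold.
#'
#' @param records Variant tibble with a `qual` column.
#' @param threshold Quality threshold (>= 0).
#' @return Filtered tibble.
#' @export
filter_by_quality <- function(records, threshold) {
  if (threshold < 0) abort("threshold must be >= 0")
  filter(records, .data$qual > threshold)
}
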