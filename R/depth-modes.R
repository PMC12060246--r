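#' Estimate the modes of a per-contig depth distribution
#'
#' Builds a length-weighted histogram of per-contig median depths at bin
#' width 1, smooths it with a centered moving average, and reports the two
#' highest local maxima separated by at least `min_separation` bins. A
#' male diploid assembly shows exactly this structure: an autosomal mode and
#' a sex-chromosome mode at about half its depth. The primary mode is the
#' higher-depth of the two peaks; `secondary` is `NA` when the histogram is
#' unimodal.
#'
#' @param depths Per-contig median depths (high-quality stratum).
#' @param weights Optional weights, typically contig lengths; default equal.
#' @param window Smoothing window (default 5).
#' @param min_separation Minimum distance in bins between the two reported
#'   modes (default 10).
#' @return A `depth_modes` object with elements `primary`, `secondary` and
#'   the smoothed `histogram` tibble.
#' @export
estimate_depth_modes <- function(depths, weights = NULL, window = 5L,
                                 min_separation = 10L) {
  if (length(depths) == 0) abort("need at least one contig depth")
  if (all(depths == 0)) abort("all depths are zero")
  weights <- weights %||% rep(1, length(depths))
  stopifnot(length(weights) == length(depths))

  bin <- round(depths)
  bins <- 0:max(bin)
  wt <- vapply(bins, function(b) sum(weights[bin == b]), numeric(1))
  sm <- smooth_counts(wt, window)
  hist_tbl <- tibble(bin = bins, weight = wt, smoothed = sm)

  peaks <- local_maxima(sm)
  peaks <- peaks[sm[peaks] > 0]
  best <- peaks[which.max(sm[peaks])]
  far <- peaks[abs(peaks - best) >= min_separation]
  second <- if (length(far) > 0) far[which.max(sm[far])] else NA_integer_

  # smoothing flattens an isolated spike into a plateau whose leftmost bin
  # would otherwise win; snap each peak to the heaviest raw bin nearby
  half <- (window - 1L) %/% 2L
  refine <- function(i) {
    if (is.na(i)) return(i)
    lo <- max(1L, i - half); hi <- min(length(wt), i + half)
    (lo:hi)[which.max(wt[lo:hi])]
  }
  best <- refine(best)
  second <- refine(second)

  mode_depths <- bins[c(best, second)]
  primary <- max(mode_depths, na.rm = TRUE)
  secondary <- if (is.na(second)) NA_real_ else min(mode_depths)

  structure(list(primary = primary, secondary = secondary,
                 histogram = hist_tbl, window = window,
                 min_separation = min_separation),
            class = "depth_modes")
}

#' @export
print.depth_modes <- function(x, ...) {
  cat("<depth_modes> primary:", x$primary, " secondary:",
      if (is.na(x$secondary)) "none" else x$secondary, "\n")
  invisible(x)
}

#' @rdname estimate_depth_modes
#' @param x A `depth_modes` object.
#' @param ... Unused.
#' @export
tidy.depth_modes <- function(x, ...) {
  tibble(mode = c("primary", "secondary"),
         depth = c(x$primary, x$secondary)) |>
    filter(!is.na(.data$depth))
}

#' @rdname estimate_depth_modes
#' @export
glance.depth_modes <- function(x, ...) {
  tibble(primary = x$primary, secondary = x$secondary,
         bimodal = !is.na(x$secondary))
}

#' @rdname estimate_depth_modes
#' @param object A `depth_modes` object.
#' @export
autoplot.depth_modes <- function(object, ...) {
  ggplot2::ggplot(object$histogram, ggplot2::aes(x = .data$bin,
                                                 y = .data$smoothed)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$weight), fill = "grey80") +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = stats::na.omit(c(object$primary,
                                                      object$secondary)),
                        linetype = "dashed") +
    ggplot2::labs(x = "median depth (fold)", y = "weighted contig count")
}
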