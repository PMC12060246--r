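#' Intersect two normalized call sets
#'
#' Splits two call sets into shared and caller-specific records by exact
#' match on (contig, pos, ref, alt). Inputs must be normalized (see
#' [normalize_variants()]); unsorted input is rejected as unnormalized.
#' Insertion/deletion designation is relative to the haploid assembly the
#' calls were made against.
#'
#' @param a,b Normalized variant tibbles.
#' @return A `callset_intersection`: list with tibbles `shared` (a's record
#'   plus `qual_b`), `a_only`, `b_only`, and per-vtype `counts`.
#' @export
intersect_callsets <- function(a, b) {
  check_sorted <- function(x, which) {
    if (nrow(x) < 2) return(invisible())
    o <- order(x$contig, x$pos, x$ref, x$alt)
    if (!identical(o, seq_len(nrow(x)))) {
      abort(sprintf("call set '%s' is not sorted; normalize it first", which))
    }
  }
  check_sorted(a, "a")
  check_sorted(b, "b")
  key <- c("contig", "pos", "ref", "alt")
  b_key <- select(b, all_of(key), qual_b = "qual")
  shared <- inner_join(a, b_key, by = key)
  a_only <- anti_join(a, b, by = key)
  b_only <- anti_join(b, a, by = key)
  counts <- bind_rows(
    mutate(count(shared, .data$vtype), set = "shared"),
    mutate(count(a_only, .data$vtype), set = "a_only"),
    mutate(count(b_only, .data$vtype), set = "b_only")
  ) |>
    select("set", "vtype", "n")
  structure(list(shared = shared, a_only = a_only, b_only = b_only,
                 counts = counts),
            class = "callset_intersection")
}

#' @export
print.callset_intersection <- function(x, ...) {
  cat("<callset_intersection> shared:", nrow(x$shared), " a_only:",
      nrow(x$a_only), " b_only:", nrow(x$b_only), "\n")
  print(x$counts)
  invisible(x)
}

#' @rdname intersect_callsets
#' @param x A `callset_intersection`.
#' @param ... Unused.
#' @export
tidy.callset_intersection <- function(x, ...) x$counts

#' @rdname intersect_callsets
#' @export
glance.callset_intersection <- function(x, ...) {
  tibble(n_shared = nrow(x$shared), n_a_only = nrow(x$a_only),
         n_b_only = nrow(x$b_only))
}
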