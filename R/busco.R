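#' Bundled BUSCO completeness summary for ten Delphinoidea assemblies
#'
#' Published compleasm category counts (single-copy complete, duplicated,
#' missing, fragmented; Laurasiatheria odb10, lineage total 12,234) for ten
#' delphinoid reference assemblies, shipped as a worked example for the
#' completeness arithmetic. The focal hourglass dolphin assembly is
#' `Lagenorhynchus cruciger`.
#'
#' @return Tibble: `species`, `single`, `duplicated`, `missing`,
#'   `fragmented`.
#' @export
delphinoidea_busco_counts <- function() {
  path <- system.file("extdata", "delphinoidea_busco_summary.tsv",
                      package = "contigqc", mustWork = TRUE)
  readr::read_tsv(path, col_types = "ciiii")
}

#' Per-category BUSCO percentages
#'
#' Percentage = count / (single + duplicated + missing + fragmented) x 100,
#' reported to two decimals (half away from zero). This denominator
#' reproduces published compleasm tables exactly.
#'
#' @param counts Tibble with columns `single`, `duplicated`, `missing`,
#'   `fragmented` (one row per species).
#' @return `counts` with `total` and `pct_*` columns added.
#' @export
completeness_percentages <- function(counts) {
  cats <- c("single", "duplicated", "missing", "fragmented")
  stopifnot(all(cats %in% names(counts)))
  if (any(rowSums(counts[cats]) == 0)) abort("zero category total")
  counts |>
    mutate(total = .data$single + .data$duplicated + .data$missing +
             .data$fragmented) |>
    mutate(across(all_of(cats),
                  ~ round_half_up(.x / total * 100, 2),
                  .names = "pct_{.col}"))
}

#' Cross-species mean of a BUSCO category
#'
#' Arithmetic mean over all species in the table (the focal species is
#' included by default; set `focal` and `include_focal = FALSE` to exclude
#' it), returned raw and rounded to the nearest integer (half away from
#' zero) for reporting.
#'
#' @param counts Count tibble (see [delphinoidea_busco_counts()]).
#' @param category One of `"single"`, `"duplicated"`, `"missing"`,
#'   `"fragmented"`.
#' @param include_focal Include the focal species in the mean?
#' @param focal Species name to drop when `include_focal = FALSE`.
#' @return One-row tibble: `category`, `n_species`, `mean_raw`,
#'   `mean_rounded`.
#' @export
category_means <- function(counts, category, include_focal = TRUE,
                           focal = NULL) {
  if (!category %in% c("single", "duplicated", "missing", "fragmented")) {
    abort(sprintf("unknown category '%s'", category))
  }
  tbl <- counts
  if (!include_focal) {
    if (is.null(focal)) abort("focal species needed when include_focal = FALSE")
    tbl <- filter(tbl, .data$species != focal)
  }
  if (nrow(tbl) == 0) abort("no species left")
  m <- mean(tbl[[category]])
  tibble(category = category, n_species = nrow(tbl), mean_raw = m,
         mean_rounded = round_half_up(m))
}

#' Upset intersections of per-BUSCO statuses
#'
#' Partitions the BUSCO-id universe by presence pattern: for each BUSCO id,
#' the exact set of species in which it has `status`. Every id belongs to
#' exactly one pattern (possibly the empty set), so pattern cardinalities
#' sum to the universe size. Patterns are ranked by cardinality, ties broken
#' by the pattern's bit order over the species list.
#'
#' @param status_map Long tibble: `species`, `busco_id`, `status`.
#' @param status Status defining membership (e.g. `"single"` or
#'   `"missing"`).
#' @param top_n Keep only the `top_n` largest patterns (`NULL` for all).
#' @param species_order Species ordering used for the pattern key; default
#'   the order of first appearance.
#' @return Tibble: `pattern` (0/1 key in species order), `species`
#'   (collapsed `+`-separated members), `n_species`, `n_busco`.
#' @export
upset_intersections <- function(status_map, status = "single", top_n = NULL,
                                species_order = NULL) {
  stopifnot(all(c("species", "busco_id", "status") %in% names(status_map)))
  species_order <- species_order %||% unique(status_map$species)
  per_species_ids <- status_map |>
    group_by(.data$species) |>
    summarise(ids = list(sort(unique(.data$busco_id))), .groups = "drop")
  universe <- sort(unique(status_map$busco_id))
  if (!all(map_int(per_species_ids$ids, length) == length(universe)) ||
        !all(map_chr(per_species_ids$ids, ~ paste(.x, collapse = "\r")) ==
               paste(universe, collapse = "\r"))) {
    abort("BUSCO id universes differ across species")
  }
  member <- status_map |>
    filter(.data$status == !!status) |>
    mutate(species = factor(.data$species, levels = species_order))
  key <- member |>
    group_by(.data$busco_id) |>
    summarise(bits = paste(sort(as.integer(.data$species)), collapse = ","),
              .groups = "drop")
  all_ids <- tibble(busco_id = universe) |>
    left_join(key, by = "busco_id") |>
    mutate(bits = coalesce(.data$bits, ""))
  pattern_key <- function(bits) {
    v <- rep("0", length(species_order))
    if (nzchar(bits)) v[as.integer(strsplit(bits, ",")[[1]])] <- "1"
    paste(v, collapse = "")
  }
  out <- all_ids |>
    count(.data$bits, name = "n_busco") |>
    mutate(pattern = map_chr(.data$bits, pattern_key),
           species = map_chr(.data$bits, function(b) {
             if (!nzchar(b)) return("")
             paste(species_order[as.integer(strsplit(b, ",")[[1]])],
                   collapse = "+")
           }),
           n_species = str_count(.data$pattern, "1")) |>
    arrange(desc(.data$n_busco), .data$pattern) |>
    select("pattern", "species", "n_species", "n_busco")
  if (!is.null(top_n)) out <- head(out, top_n)
  out
}

#' Adjust missingness for ancestrally lost BUSCOs
#'
#' BUSCOs missing from every assembly in a clade were plausibly lost in the
#' common ancestor, not by assembly error. Subtracting them from each
#' species' missing count (and from the lineage total) gives an
#' assembly-quality-only missingness.
#'
#' @param counts Count tibble (see [delphinoidea_busco_counts()]).
#' @param missing_in_all Number of BUSCOs missing in every species; must not
#'   exceed any species' missing count.
#' @return List: `per_species` tibble with `adjusted_missing` and
#'   `adjusted_total`, plus `adjusted_mean_missing` (raw and rounded).
#' @export
ancestral_missing_adjustment <- function(counts, missing_in_all) {
  if (missing_in_all > min(counts$missing)) {
    abort("missing_in_all exceeds some species' missing count")
  }
  per_species <- counts |>
    mutate(total = .data$single + .data$duplicated + .data$missing +
             .data$fragmented,
           adjusted_missing = .data$missing - missing_in_all,
           adjusted_total = .data$total - missing_in_all)
  m <- mean(per_species$adjusted_missing)
  list(per_species = per_species,
       adjusted_mean_missing_raw = m,
       adjusted_mean_missing = round_half_up(m))
}
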