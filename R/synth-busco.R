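#' Generate a multi-species BUSCO status fixture with planted structure
#'
#' Builds a species-by-BUSCO status table with known set structure:
#' exactly `ancestral_missing` BUSCO ids missing in every species (the
#' ancestral-loss signal), each requested lineage-specific set planted
#' verbatim, and every remaining id single-copy complete in all species.
#'
#' @param n_species Number of species (named `sp01`, `sp02`, ...).
#' @param n_busco Size of the BUSCO universe.
#' @param ancestral_missing Number of ids missing in all species.
#' @param lineage_specific List of planted sets; each element is a list
#'   with `n` (set size), `status` (the status the member species get,
#'   `"single"` or `"missing"`) and `species` (character vector of member
#'   species). Non-member species get the complementary status.
#' @param seed Integer seed (shuffles which ids land in which set).
#' @return List: `status_map` (long tibble `species`, `busco_id`,
#'   `status`), `counts` (per-species category counts), `truth`
#'   (per-BUSCO-id planted set).
#' @export
generate_busco_fixture <- function(n_species = 10L, n_busco = 12234L,
                                   ancestral_missing = 33L,
                                   lineage_specific = list(
                                     list(n = 122L, status = "single",
                                          species = sprintf("sp%02d", 1:9)),
                                     list(n = 50L, status = "single",
                                          species = sprintf("sp%02d", 2:10)),
                                     list(n = 13L, status = "single",
                                          species = "sp01"),
                                     list(n = 9L, status = "single",
                                          species = sprintf("sp%02d",
                                                            c(1:4, 7:10)))),
                                   seed = 1L) {
  species <- sprintf("sp%02d", seq_len(n_species))
  planted_n <- sum(map_int(lineage_specific, ~ as.integer(.x$n)))
  if (ancestral_missing + planted_n > n_busco) {
    abort("infeasible set sizes: ancestral_missing + planted sets exceed n_busco")
  }
  for (ls in lineage_specific) {
    if (!all(ls$species %in% species)) {
      abort("lineage_specific species outside the species list")
    }
  }
  local_seed(seed, {
    ids <- sprintf("busco_%05d", sample.int(n_busco))
    cursor <- 0L
    take <- function(k) {
      out <- ids[cursor + seq_len(k)]
      cursor <<- cursor + k
      out
    }
    truth_rows <- list()
    status_rows <- list()

    anc <- take(ancestral_missing)
    if (ancestral_missing > 0) {
      truth_rows[["anc"]] <- tibble(busco_id = anc, planted = "missing_in_all")
      status_rows[["anc"]] <- tidyr::expand_grid(species = species,
                                                 busco_id = anc) |>
        mutate(status = "missing")
    }
    for (i in seq_along(lineage_specific)) {
      ls <- lineage_specific[[i]]
      set_ids <- take(ls$n)
      lab <- sprintf("planted_set_%02d", i)
      truth_rows[[lab]] <- tibble(busco_id = set_ids, planted = lab)
      other <- if (ls$status == "single") "missing" else "single"
      status_rows[[lab]] <- tidyr::expand_grid(species = species,
                                               busco_id = set_ids) |>
        mutate(status = if_else(.data$species %in% ls$species,
                                ls$status, other))
    }
    rest <- if (cursor < n_busco) ids[(cursor + 1L):n_busco] else character(0)
    if (length(rest) > 0) {
      truth_rows[["rest"]] <- tibble(busco_id = rest,
                                     planted = "single_in_all")
      status_rows[["rest"]] <- tidyr::expand_grid(species = species,
                                                  busco_id = rest) |>
        mutate(status = "single")
    }
    status_map <- list_rbind(status_rows) |>
      arrange(.data$species, .data$busco_id)
    counts <- status_map |>
      count(.data$species, .data$status) |>
      tidyr::pivot_wider(names_from = "status", values_from = "n",
                         values_fill = 0L)
    for (col in c("single", "duplicated", "missing", "fragmented")) {
      if (!col %in% names(counts)) counts[[col]] <- 0L
    }
    counts <- select(counts, "species", "single", "duplicated", "missing",
                     "fragmented")
    list(status_map = status_map,
         counts = counts,
         truth = list_rbind(truth_rows))
  })
}
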