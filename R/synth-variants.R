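#' Simulate a pair of overlapping variant call sets
#'
#' Plants true heterozygous SNVs and indels at each contig's truth rates,
#' then emits two call sets: every true variant appears in both at a
#' high-quality mode, and each caller adds its own false calls at a
#' low-quality mode, giving both quality histograms the bimodal shape with
#' a valley that [detect_quality_dip()] looks for. Exonic indels are
#' thinned relative to intronic ones, and frame-disrupting exonic indels
#' are thinned further (purifying-selection emulation). The second call
#' set is phased: its true heterozygous records carry PS tags forming a
#' planted number of phase blocks per contig, allotted so that ~55% of
#' eligible contigs are a single block and ~80% at most three.
#'
#' @param genome Named character vector of contig sequences.
#' @param annotation Annotation tibble from [generate_annotation()].
#' @param truth Per-contig truth tibble from [generate_assembly()].
#' @param seed Integer seed.
#' @param quality_modes List with entries `a` and `b`, each a list
#'   `error = c(mean, sd)`, `true = c(mean, sd)`; error and true means must
#'   be >= 10 quality units apart. Defaults place the mixture valleys at
#'   quality 14 (caller a) and 20 (caller b).
#' @param error_rate False calls per caller as a fraction of its true-call
#'   count.
#' @param exon_indel_keep Probability an exonic indel survives thinning.
#' @param frameshift_keep Additional survival probability for exonic
#'   frame-disrupting indels (total keep = `exon_indel_keep *
#'   frameshift_keep`).
#' @param block_quota Cumulative quota `c(single, le3)` controlling planted
#'   phase-block counts.
#' @return List: `a`, `b` (sorted variant tibbles; `b` carries
#'   `phase_set`), `variant_truth` (per-variant caller membership,
#'   error flag and quality mode), `phase_truth` (planted blocks per
#'   contig), `dips` (numerically computed valley of each caller's realized
#'   quality mixture).
#' @export
simulate_callsets <- function(genome, annotation, truth, seed = 1L,
                              quality_modes = list(
                                a = list(error = c(8, 2), true = c(30, 6.5)),
                                b = list(error = c(12, 2.5), true = c(38, 7))),
                              error_rate = 0.3,
                              exon_indel_keep = 0.3,
                              frameshift_keep = 0.2,
                              block_quota = c(0.55, 0.80)) {
  for (cl in c("a", "b")) {
    sep <- quality_modes[[cl]]$true[1] - quality_modes[[cl]]$error[1]
    if (sep < 10) abort(sprintf(
      "caller %s: true and error quality modes must be >= 10 units apart", cl))
  }
  index <- build_annotation_index(annotation,
                                  setNames(truth$length, truth$contig_id))
  local_seed(seed, {
    true_vars <- draw_true_variants(genome, truth, index, exon_indel_keep,
                                    frameshift_keep)
    err_a <- draw_error_calls(genome, truth, round(error_rate * nrow(true_vars)),
                              exclude = true_vars, tag = "ea")
    err_b <- draw_error_calls(genome, truth, round(error_rate * nrow(true_vars)),
                              exclude = bind_rows(true_vars, err_a), tag = "eb")

    variant_truth <- bind_rows(
      mutate(true_vars, caller = "both", is_error = FALSE,
             quality_mode = "true"),
      mutate(err_a, caller = "a_only", is_error = TRUE,
             quality_mode = "error"),
      mutate(err_b, caller = "b_only", is_error = TRUE,
             quality_mode = "error")
    )

    draw_qual <- function(n, mode) {
      pmin(60, pmax(1, round(rnorm(n, mode[1], mode[2]))))
    }

    rec_a <- bind_rows(
      mutate(true_vars, qual = draw_qual(n(), quality_modes$a$true)),
      mutate(err_a, qual = draw_qual(n(), quality_modes$a$error))
    ) |>
      mutate(genotype = "0/1", phase_set = NA_integer_) |>
      arrange(.data$contig, .data$pos, .data$ref, .data$alt)

    phase <- plant_phase_blocks(true_vars, block_quota)
    rec_b <- bind_rows(
      true_vars |>
        mutate(qual = draw_qual(n(), quality_modes$b$true)) |>
        left_join(phase$assignment, by = c("contig", "pos")) |>
        mutate(genotype = "0|1"),
      mutate(err_b, qual = draw_qual(n(), quality_modes$b$error),
             genotype = "0/1", phase_set = NA_integer_)
    ) |>
      arrange(.data$contig, .data$pos, .data$ref, .data$alt)

    dips <- bind_rows(
      tibble(caller = "a",
             planted_dip = mixture_valley(quality_modes$a, nrow(true_vars),
                                          nrow(err_a))),
      tibble(caller = "b",
             planted_dip = mixture_valley(quality_modes$b, nrow(true_vars),
                                          nrow(err_b)))
    )

    sel <- c("contig", "pos", "ref", "alt", "vtype", "qual", "genotype",
             "phase_set")
    list(a = select(rec_a, all_of(sel)),
         b = select(rec_b, all_of(sel)),
         variant_truth = variant_truth,
         phase_truth = phase$per_contig,
         dips = dips)
  })
}

# Integer quality at which the realized two-component normal mixture is
# lowest between its modes.
mixture_valley <- function(modes, n_true, n_err) {
  lo <- ceiling(modes$error[1])
  hi <- floor(modes$true[1])
  grid <- lo:hi
  dens <- n_err * dnorm(grid, modes$error[1], modes$error[2]) +
    n_true * dnorm(grid, modes$true[1], modes$true[2])
  grid[which.min(dens)]
}

# True heterozygous variants at class rates, with exonic-indel thinning.
draw_true_variants <- function(genome, truth, index, exon_indel_keep,
                               frameshift_keep) {
  rows <- pmap(list(truth$contig_id, truth$length, truth$het_snv_rate,
                    truth$het_indel_rate),
               function(id, len, snv_rate, indel_rate) {
    s <- toupper(genome[[id]])
    usable <- 10L:(len - 10L)
    n_snv <- rbinom(1, len, snv_rate)
    n_indel <- rbinom(1, len, indel_rate)
    if (n_snv + n_indel == 0) return(NULL)
    pos <- sample(usable, min(n_snv + n_indel, length(usable)))
    is_snv <- seq_along(pos) <= n_snv
    bases <- c("A", "C", "G", "T")
    recs <- map2(pos, is_snv, function(p, snv) {
      refb <- substr(s, p, p)
      if (!refb %in% bases) return(NULL)
      if (snv) {
        tibble(contig = id, pos = p, ref = refb,
               alt = sample(setdiff(bases, refb), 1), vtype = "snv")
      } else {
        ilen <- min(1L + rgeom(1, 0.7), 6L)
        if (runif(1) < 0.5) {
          tibble(contig = id, pos = p, ref = refb,
                 alt = paste0(refb, paste(sample(bases, ilen, replace = TRUE),
                                          collapse = "")),
                 vtype = "ins")
        } else {
          del <- substr(s, p, p + ilen)
          if (str_detect(del, "[^ACGT]")) return(NULL)
          tibble(contig = id, pos = p, ref = del, alt = refb, vtype = "del")
        }
      }
    })
    list_rbind(recs[!vapply(recs, is.null, logical(1))])
  })
  vars <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(vars) || nrow(vars) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), vtype = character()))
  }
  # resolve collisions: keep the first draw at each (contig, pos)
  n0 <- nrow(vars)
  vars <- distinct(vars, .data$contig, .data$pos, .keep_all = TRUE)
  if (nrow(vars) < n0) {
    inform(sprintf("dropped %d colliding variant draw(s)", n0 - nrow(vars)))
  }
  # purifying-selection thinning of exonic indels
  vars <- assign_regions(vars, index)
  keep <- runif(nrow(vars))
  thin <- vars$vtype != "snv" & vars$region == "exon"
  frameshift <- thin &
    (abs(nchar(vars$ref) - nchar(vars$alt)) %% 3L != 0L)
  p_keep <- rep(1, nrow(vars))
  p_keep[thin] <- exon_indel_keep
  p_keep[frameshift] <- exon_indel_keep * frameshift_keep
  vars |>
    filter(keep < p_keep) |>
    select("contig", "pos", "ref", "alt", "vtype") |>
    mutate(pos = as.integer(.data$pos))
}

# Caller-specific false calls at random positions (SNV-biased).
draw_error_calls <- function(genome, truth, n_err, exclude, tag) {
  if (n_err == 0 || nrow(truth) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), vtype = character()))
  }
  wt <- truth$length / sum(truth$length)
  ct <- sample(truth$contig_id, n_err, replace = TRUE, prob = wt)
  lens <- setNames(truth$length, truth$contig_id)
  bases <- c("A", "C", "G", "T")
  recs <- map(seq_len(n_err), function(i) {
    id <- ct[i]
    p <- sample(10L:(lens[[id]] - 10L), 1)
    s <- toupper(genome[[id]])
    refb <- substr(s, p, p)
    if (!refb %in% bases) return(NULL)
    if (runif(1) < 0.8) {
      tibble(contig = id, pos = p, ref = refb,
             alt = sample(setdiff(bases, refb), 1), vtype = "snv")
    } else if (runif(1) < 0.5) {
      tibble(contig = id, pos = p, ref = refb,
             alt = paste0(refb, sample(bases, 1)), vtype = "ins")
    } else {
      del <- substr(s, p, p + 1L)
      if (str_detect(del, "[^ACGT]")) return(NULL)
      tibble(contig = id, pos = p, ref = del, alt = refb, vtype = "del")
    }
  })
  out <- list_rbind(recs[!vapply(recs, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), vtype = character()))
  }
  out <- distinct(out, .data$contig, .data$pos, .keep_all = TRUE)
  anti_join(out, exclude, by = c("contig", "pos")) |>
    mutate(pos = as.integer(.data$pos))
}

# Allot planted block counts by quota over contigs with >= 1 true het site,
# then cut each contig's sorted het positions into that many contiguous
# blocks. PS value = position of the first record in the block (the usual
# phasing convention).
plant_phase_blocks <- function(true_vars, block_quota) {
  contigs <- sort(unique(true_vars$contig))
  n <- length(contigs)
  if (n == 0) {
    return(list(assignment = tibble(contig = character(), pos = integer(),
                                    phase_set = integer()),
                per_contig = tibble(contig = character(),
                                    n_blocks = integer())))
  }
  n1 <- round(block_quota[1] * n)
  n_le3 <- round(block_quota[2] * n)
  n23 <- max(0L, n_le3 - n1)
  counts <- c(rep(1L, n1),
              rep(2L, ceiling(n23 / 2)), rep(3L, floor(n23 / 2)),
              sample(4:6, max(0L, n - n_le3), replace = TRUE))
  counts <- counts[seq_len(n)]
  counts <- sample(counts)  # random contig <-> count pairing

  per_contig <- tibble(contig = contigs, n_blocks = counts)
  assignment <- map2(contigs, counts, function(ctg, k) {
    p <- sort(true_vars$pos[true_vars$contig == ctg])
    k <- min(k, length(p))
    cuts <- if (k > 1) sort(sample(length(p) - 1L, k - 1L)) else integer(0)
    block_of <- findInterval(seq_along(p), c(0L, cuts) + 1L)
    ps <- tapply(p, block_of, min)[as.character(block_of)]
    tibble(contig = ctg, pos = as.integer(p),
           phase_set = as.integer(ps))
  }) |> list_rbind()
  per_contig$n_blocks <- assignment |>
    group_by(.data$contig) |>
    summarise(k = n_distinct(.data$phase_set)) |>
    arrange(match(.data$contig, contigs)) |>
    pull(.data$k)
  list(assignment = assignment, per_contig = per_contig)
}
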