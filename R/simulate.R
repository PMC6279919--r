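# Two-species synthetic diel data with known ground truth.
#
# Rhythmic genes follow baseline + A * max(0, cos(2*pi*(t - phase)/24))^k
# plus i.i.d. Gaussian noise truncated at zero; k = 1 gives the rectified
# cosine shape, k >= 3 a sharper peak. Arrhythmic genes are baseline plus
# noise. One replicate per time point.

simulate_profiles <- function(truth, grid, period = 24) {
  t(vapply(seq_len(nrow(truth)), function(i) {
    g <- truth[i, ]
    signal <- if (g$is_rhythmic) {
      k <- if (g$waveform == "peaked") g$peak_exponent else 1
      g$true_amplitude * pmax(0, cos(2 * pi * (grid - g$true_phase_h) / period))^k
    } else {
      0
    }
    pmax(0, g$baseline + signal + stats::rnorm(length(grid), 0, g$noise_sd))
  }, numeric(length(grid))))
}

make_truth <- function(gene_id, is_rhythmic, grid, baseline_range,
                       amplitude_range, noise_frac, peaked_frac,
                       peak_exponent, phases = NULL) {
  n <- length(gene_id)
  n_r <- sum(is_rhythmic)
  waveform <- rep(NA_character_, n)
  if (n_r > 0L) {
    n_peaked <- round(peaked_frac * n_r)
    waveform[is_rhythmic] <- sample(rep(c("peaked", "cosine"),
                                        c(n_peaked, n_r - n_peaked)))
  }
  phase <- rep(NA_real_, n)
  phase[is_rhythmic] <- if (is.null(phases)) {
    sample(grid, n_r, replace = TRUE)
  } else {
    rep_len(phases, n_r)
  }
  amplitude <- ifelse(is_rhythmic,
                      stats::runif(n, amplitude_range[1], amplitude_range[2]), 0)
  baseline <- stats::runif(n, baseline_range[1], baseline_range[2])
  # noise tracks the amplitude for rhythmic genes and, CV-style, the
  # baseline for arrhythmic genes
  noise_sd <- noise_frac * ifelse(is_rhythmic, amplitude, baseline)
  tibble::tibble(
    gene_id = gene_id, is_rhythmic = is_rhythmic, waveform = waveform,
    true_phase_h = phase, true_amplitude = amplitude, baseline = baseline,
    noise_sd = noise_sd, peak_exponent = peak_exponent
  )
}

#' Simulate a single-species diel expression matrix with known truth
#'
#' Generates one 24-h cycle of FPKM profiles for a mixture of rhythmic and
#' arrhythmic genes. Rhythmic profiles are half-wave rectified cosines
#' (`waveform = "cosine"`) or their `peak_exponent`-th power
#' (`waveform = "peaked"`), scaled by a per-gene amplitude over a per-gene
#' baseline, with i.i.d. Gaussian noise truncated at zero. The noise
#' standard deviation is `noise_frac` times the amplitude for rhythmic
#' genes and `noise_frac` times the baseline for arrhythmic genes. Exactly
#' `round(frac_rhythmic * n_genes)` genes are rhythmic, and the whole
#' draw is deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param frac_rhythmic Proportion of rhythmic genes, in [0, 1].
#' @param grid Uniform sampling hours spanning one period.
#' @param period Cycle length in hours.
#' @param species Species label attached to the matrix and used as the
#'   gene-ID prefix.
#' @param baseline_range,amplitude_range Uniform draw ranges (FPKM).
#' @param noise_frac Noise standard deviation as a fraction of the
#'   amplitude (rhythmic) or baseline (arrhythmic).
#' @param peaked_frac Fraction of rhythmic genes given the peaked waveform.
#' @param peak_exponent Sharpness of the peaked waveform (>= 3).
#' @param phases Optional fixed phase call(s) for the rhythmic genes,
#'   recycled; by default phases are drawn uniformly from the grid.
#' @param seed Optional integer seed.
#' @return A list with `expr` (a diel expression tibble) and `truth` (a
#'   tibble with `gene_id`, `is_rhythmic`, `waveform`, `true_phase_h`,
#'   `true_amplitude`, `baseline`, `noise_sd`).
#' @examples
#' sim <- simulate_diel_matrix(20, 0.5, seed = 1)
#' sum(sim$truth$is_rhythmic)
#' @export
simulate_diel_matrix <- function(n_genes, frac_rhythmic,
                                 grid = seq(2, 24, by = 2), period = 24,
                                 species = "spA",
                                 baseline_range = c(2, 10),
                                 amplitude_range = c(5, 50),
                                 noise_frac = 0.2, peaked_frac = 0.5,
                                 peak_exponent = 4, phases = NULL,
                                 seed = NULL) {
  check_uniform_grid(grid, period)
  if (frac_rhythmic < 0 || frac_rhythmic > 1) {
    rlang::abort("`frac_rhythmic` must lie in [0, 1].")
  }
  with_seed(seed, {
    n_r <- round(frac_rhythmic * n_genes)
    gene_id <- sprintf("%s_g%04d", species, seq_len(n_genes))
    is_rhythmic <- seq_len(n_genes) <= n_r
    truth <- make_truth(gene_id, is_rhythmic, grid, baseline_range,
                        amplitude_range, noise_frac, peaked_frac,
                        peak_exponent, phases)
    m <- simulate_profiles(truth, grid, period)
    rownames(m) <- gene_id
    list(
      expr = values_to_expr(m, grid, species = species),
      truth = truth[, setdiff(names(truth), "peak_exponent")]
    )
  })
}

check_uniform_grid <- function(grid, period) {
  if (length(grid) < 2L || is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("`grid` must be strictly increasing with at least 2 points.")
  }
  steps <- diff(grid)
  if (max(abs(steps - steps[1])) > 1e-9) {
    rlang::abort("`grid` must be uniform.")
  }
  if (abs((grid[length(grid)] - grid[1]) + steps[1] - period) > 1e-9) {
    rlang::abort("`grid` must span exactly one period.")
  }
  invisible(grid)
}

#' Simulate a two-species ortholog scenario with known conservation types
#'
#' Builds two species' diel matrices plus an ortholog-group table engineered
#' so that classifying the groups with the ground-truth rhythmic sets
#' reproduces the requested count of each rhythmicity-conservation type:
#' Type 1 groups hold one rhythmic gene per species; Type 2 a rhythmic
#' species-A gene with an arrhythmic species-B ortholog; Type 3 the mirror;
#' Type 4 and 5 a rhythmic gene with no ortholog in the other species.
#' Additional arrhythmic filler genes (outside any group) pad each species
#' to `n_genes_per_species`; if `frac_rhythmic` asks for more rhythmic
#' genes than the types require, the extras join existing Type 1 groups as
#' additional rhythmic members, which leaves every type count unchanged.
#'
#' @param type_counts Named vector/list with entries `T1`..`T5`: the number
#'   of ortholog groups of each type.
#' @param n_genes_per_species Total genes per species (default: just the
#'   genes the types require).
#' @param frac_rhythmic Optional proportion of rhythmic genes per species;
#'   must be achievable given `type_counts` (extras go to Type 1 groups).
#' @param species Length-2 character vector of species labels.
#' @param seed Optional integer seed.
#' @inheritParams simulate_diel_matrix
#' @param ... Further arguments passed to the per-species generator
#'   (`baseline_range`, `amplitude_range`, `noise_frac`, ...).
#' @return A list with `expr_a`, `expr_b`, `truth_a`, `truth_b`, and
#'   `groups` (tibble of `group_id`, `gene_id`).
#' @examples
#' sc <- simulate_ortholog_scenario(c(T1 = 2, T2 = 1, T3 = 1, T4 = 1, T5 = 1),
#'                                  seed = 1)
#' nrow(sc$groups)
#' @export
simulate_ortholog_scenario <- function(type_counts,
                                       n_genes_per_species = NULL,
                                       frac_rhythmic = NULL,
                                       grid = seq(2, 24, by = 2), period = 24,
                                       species = c("spA", "spB"),
                                       baseline_range = c(2, 10),
                                       amplitude_range = c(5, 50),
                                       noise_frac = 0.2, peaked_frac = 0.5,
                                       peak_exponent = 4,
                                       seed = NULL) {
  tc <- as.list(type_counts)
  need <- c("T1", "T2", "T3", "T4", "T5")
  if (!all(need %in% names(tc))) {
    rlang::abort("`type_counts` must name T1, T2, T3, T4, T5.")
  }
  tc <- lapply(tc[need], as.integer)
  if (any(unlist(tc) < 0L)) rlang::abort("type counts must be non-negative.")

  # genes demanded by the group structure, per species
  need_r_a <- tc$T1 + tc$T2 + tc$T4
  need_r_b <- tc$T1 + tc$T3 + tc$T5
  need_arr_a <- tc$T3
  need_arr_b <- tc$T2
  min_a <- need_r_a + need_arr_a
  min_b <- need_r_b + need_arr_b
  n_a <- n_genes_per_species %||% min_a
  n_b <- n_genes_per_species %||% min_b
  if (n_a < min_a || n_b < min_b) {
    rlang::abort("`n_genes_per_species` is too small for `type_counts`.")
  }
  extra_r_a <- extra_r_b <- 0L
  if (!is.null(frac_rhythmic)) {
    extra_r_a <- round(frac_rhythmic * n_a) - need_r_a
    extra_r_b <- round(frac_rhythmic * n_b) - need_r_b
    if (extra_r_a < 0L || extra_r_b < 0L) {
      rlang::abort("`frac_rhythmic` implies fewer rhythmic genes than `type_counts` requires.")
    }
    if ((extra_r_a > 0L || extra_r_b > 0L) && tc$T1 == 0L) {
      rlang::abort("extra rhythmic genes need at least one Type 1 group to join.")
    }
    if (need_r_a + extra_r_a + need_arr_a > n_a ||
        need_r_b + extra_r_b + need_arr_b > n_b) {
      rlang::abort("`frac_rhythmic` and `type_counts` exceed `n_genes_per_species`.")
    }
  }

  with_seed(seed, {
    build_side <- function(n, need_r, extra_r, need_arr, sp) {
      gene_id <- sprintf("%s_g%04d", sp, seq_len(n))
      is_r <- seq_len(n) <= need_r + extra_r
      truth <- make_truth(gene_id, is_r, grid, baseline_range,
                          amplitude_range, noise_frac, peaked_frac,
                          peak_exponent)
      m <- simulate_profiles(truth, grid, period)
      rownames(m) <- gene_id
      list(expr = values_to_expr(m, grid, species = sp), truth = truth)
    }
    a <- build_side(n_a, need_r_a, extra_r_a, need_arr_a, species[1])
    b <- build_side(n_b, need_r_b, extra_r_b, need_arr_b, species[2])

    rhythm_a <- a$truth$gene_id[a$truth$is_rhythmic]
    rhythm_b <- b$truth$gene_id[b$truth$is_rhythmic]
    arr_a <- a$truth$gene_id[!a$truth$is_rhythmic]
    arr_b <- b$truth$gene_id[!b$truth$is_rhythmic]

    take <- function(pool, k, used) utils::head(setdiff(pool, used), k)
    used_a <- used_b <- character()
    groups <- list()
    gid <- 0L
    add_group <- function(members) {
      gid <<- gid + 1L
      groups[[gid]] <<- tibble::tibble(
        group_id = sprintf("OG%05d", gid), gene_id = members
      )
    }
    for (i in seq_len(tc$T1)) {
      ga <- take(rhythm_a, 1L, used_a); gb <- take(rhythm_b, 1L, used_b)
      used_a <- c(used_a, ga); used_b <- c(used_b, gb)
      add_group(c(ga, gb))
    }
    for (i in seq_len(tc$T2)) {
      ga <- take(rhythm_a, 1L, used_a); gb <- take(arr_b, 1L, used_b)
      used_a <- c(used_a, ga); used_b <- c(used_b, gb)
      add_group(c(ga, gb))
    }
    for (i in seq_len(tc$T3)) {
      ga <- take(arr_a, 1L, used_a); gb <- take(rhythm_b, 1L, used_b)
      used_a <- c(used_a, ga); used_b <- c(used_b, gb)
      add_group(c(ga, gb))
    }
    for (i in seq_len(tc$T4)) {
      ga <- take(rhythm_a, 1L, used_a)
      used_a <- c(used_a, ga)
      add_group(ga)
    }
    for (i in seq_len(tc$T5)) {
      gb <- take(rhythm_b, 1L, used_b)
      used_b <- c(used_b, gb)
      add_group(gb)
    }
    groups <- dplyr::bind_rows(groups)

    # leftover rhythmic genes would otherwise classify as Type 4/5
    # singletons: attach them to Type 1 groups, which stay Type 1
    t1_ids <- sprintf("OG%05d", seq_len(tc$T1))
    leftover <- c(setdiff(rhythm_a, c(used_a, groups$gene_id)),
                  setdiff(rhythm_b, c(used_b, groups$gene_id)))
    if (length(leftover) > 0L) {
      groups <- dplyr::bind_rows(groups, tibble::tibble(
        group_id = sample(t1_ids, length(leftover), replace = TRUE),
        gene_id = leftover
      ))
    }
    list(expr_a = a$expr, expr_b = b$expr,
         truth_a = a$truth, truth_b = b$truth,
         groups = dplyr::arrange(groups, .data$group_id, .data$gene_id))
  })
}

#' Write and read ortholog groups as two-column TSV
#'
#' The on-disk format is `group_id<TAB>gene_id`, one member per line, with
#' a header row; `#` lines are comments.
#'
#' @param groups A tibble with `group_id` and `gene_id` columns.
#' @param path File path.
#' @return `read_ortholog_groups()` returns the groups tibble;
#'   `write_ortholog_groups()` returns `path` invisibly.
#' @export
write_ortholog_groups <- function(groups, path) {
  readr::write_tsv(groups[, c("group_id", "gene_id")], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_ortholog_groups
#' @export
read_ortholog_groups <- function(path) {
  out <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(out) < 2L) rlang::abort(sprintf("'%s' is not a two-column group file.", path))
  names(out)[1:2] <- c("group_id", "gene_id")
  out[, 1:2]
}
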