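#' Diel expression tables
#'
#' Throughout the package a diel expression time course is a tibble whose
#' first column is `gene_id` and whose remaining columns are FPKM values at
#' the sampled hours, with column names equal to the hour after first light
#' (e.g. `"2"`, `"4"`, ..., `"24"`). Hours lie in (0, 24] and increase left
#' to right; day is (0, 12] and night is (12, 24]. A `species` attribute may
#' tag the table but is never required.
#'
#' @param expr A diel expression tibble.
#' @return `diel_grid()` returns the numeric sampling grid in hours.
#' @examples
#' sim <- simulate_diel_matrix(n_genes = 5, frac_rhythmic = 0.4, seed = 1)
#' diel_grid(sim$expr)
#' @export
diel_grid <- function(expr) {
  check_expr(expr)
  as.numeric(names(expr)[-1])
}

check_expr <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || ncol(expr) < 2L || names(expr)[1] != "gene_id") {
    rlang::abort(sprintf(
      "`%s` must be a tibble with a `gene_id` first column and hour-named value columns.",
      arg
    ))
  }
  grid <- suppressWarnings(as.numeric(names(expr)[-1]))
  if (anyNA(grid)) {
    rlang::abort(sprintf("`%s` has non-numeric time-point column names.", arg))
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    rlang::abort(sprintf("`%s` time points must be strictly increasing.", arg))
  }
  if (anyDuplicated(expr$gene_id)) {
    dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
    rlang::abort(sprintf(
      "duplicate gene IDs in `%s`: %s", arg,
      paste(utils::head(dup, 5L), collapse = ", ")
    ))
  }
  invisible(expr)
}

expr_values <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

expr_species <- function(expr) attr(expr, "species") %||% NA_character_

set_expr_species <- function(expr, species) {
  attr(expr, "species") <- species
  expr
}

values_to_expr <- function(m, grid, species = NULL) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  names(out) <- as.character(grid)
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
  if (!is.null(species)) out <- set_expr_species(out, species)
  out
}

#' Read a diel expression matrix from TSV
#'
#' Reads a tab-separated gene-by-time-point FPKM table. The header row holds
#' the gene-ID column name followed by numeric sampling hours; `#` lines are
#' treated as comments. Malformed rows are reported with their line numbers.
#'
#' @param path Path to a TSV file.
#' @param species Optional species label stored as an attribute.
#' @return A diel expression tibble (see [diel_grid()]).
#' @export
read_expression <- function(path, species = NULL) {
  raw <- readr::read_tsv(
    path,
    comment = "#", col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    rlang::abort(sprintf("'%s' holds no expression data.", path))
  }
  names(raw)[1] <- "gene_id"
  grid <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(grid)) {
    rlang::abort(sprintf("'%s': header time points are not all numeric.", path))
  }
  vals <- suppressWarnings(
    purrr::map(raw[-1], as.numeric)
  )
  bad_rows <- sort(unique(unlist(
    purrr::map(seq_along(vals), function(j) {
      which(is.na(vals[[j]]) & !is.na(raw[[j + 1L]]))
    })
  )))
  if (length(bad_rows) > 0L) {
    # +1: header occupies the first file line
    rlang::abort(sprintf(
      "'%s': non-numeric expression values on line(s) %s.",
      path, paste(utils::head(bad_rows + 1L, 10L), collapse = ", ")
    ))
  }
  out <- dplyr::bind_cols(tibble::tibble(gene_id = raw$gene_id), tibble::as_tibble(vals))
  check_expr(out)
  if (!is.null(species)) out <- set_expr_species(out, species)
  out
}

#' Write a diel expression matrix as TSV
#'
#' @param expr A diel expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  check_expr(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

#' Drop genes that never reach a minimum expression level
#'
#' Retains exactly the genes whose maximum FPKM across time points is at
#' least `min_max_fpkm` (the default removes genes with max FPKM < 1, the
#' conventional noise floor for FPKM time courses). Gene order is preserved
#' and the filter is idempotent.
#'
#' @param expr A diel expression tibble.
#' @param min_max_fpkm Minimum peak FPKM a gene must reach to be kept.
#' @return The filtered tibble.
#' @export
filter_low_expression <- function(expr, min_max_fpkm = 1) {
  check_expr(expr)
  m <- expr_values(expr)
  keep <- apply(m, 1L, max) >= min_max_fpkm
  expr[keep, , drop = FALSE]
}

#' Resample a diel time course with shape-preserving cubic interpolation
#'
#' Interpolates each gene's profile onto `target_grid` with the piecewise
#' cubic Hermite interpolating polynomial (pchip), which reproduces source
#' values at the original time points exactly and never overshoots on
#' monotone segments. Target hours outside the sampled range are served by
#' periodic extension of the 24-h cycle: the sample one period away is
#' copied in before interpolating (e.g. a series sampled at 4..24 h is
#' extended with its 24-h value at hour 0 so that hour 2 can be
#' interpolated).
#'
#' @param expr A diel expression tibble.
#' @param target_grid Hours to interpolate onto, strictly increasing,
#'   within (0, 24].
#' @param period Cycle length in hours used for the periodic extension.
#' @return A diel expression tibble on `target_grid`.
#' @export
resample_pchip <- function(expr, target_grid, period = 24) {
  check_expr(expr)
  grid <- diel_grid(expr)
  if (length(grid) < 2L) {
    rlang::abort("at least 2 source time points are required for interpolation.")
  }
  target_grid <- as.numeric(target_grid)
  if (is.unsorted(target_grid, strictly = TRUE)) {
    rlang::abort("`target_grid` must be strictly increasing.")
  }
  m <- expr_values(expr)
  src_t <- grid
  pre <- min(target_grid) < min(grid)
  post <- max(target_grid) > max(grid)
  if (pre) src_t <- c(grid[length(grid)] - period, src_t)
  if (post) src_t <- c(src_t, grid[1L] + period)
  if (min(target_grid) < min(src_t) || max(target_grid) > max(src_t)) {
    rlang::abort("`target_grid` lies outside one periodic extension of the source grid.")
  }
  out <- t(apply(m, 1L, function(y) {
    src_y <- y
    if (pre) src_y <- c(y[length(y)], src_y)
    if (post) src_y <- c(src_y, y[1L])
    pracma::pchip(src_t, src_y, target_grid)
  }))
  rownames(out) <- expr$gene_id
  res <- values_to_expr(out, target_grid)
  sp <- expr_species(expr)
  if (!is.na(sp)) res <- set_expr_species(res, sp)
  res
}

#' Z-score expression profiles gene-wise
#'
#' Centres and scales each gene's profile to mean 0 and standard deviation 1,
#' the transform used for phase-ordered heat maps. Constant profiles carry no
#' shape information; they are emitted as all zeros with a warning.
#'
#' @param expr A diel expression tibble.
#' @return A diel expression tibble of z-scores.
#' @export
zscore_expression <- function(expr) {
  check_expr(expr)
  m <- expr_values(expr)
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  flat <- sdv == 0 | is.na(sdv)
  if (any(flat)) {
    rlang::warn(sprintf(
      "%d constant gene(s) z-scored to all zeros: %s",
      sum(flat), paste(utils::head(expr$gene_id[flat], 5L), collapse = ", ")
    ))
    sdv[flat] <- 1
  }
  z <- (m - mu) / sdv
  res <- values_to_expr(z, diel_grid(expr))
  sp <- expr_species(expr)
  if (!is.na(sp)) res <- set_expr_species(res, sp)
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x
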