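# Core-clock candidate profiling: circadian parameters plus the
# amplitude / fold-change / JTK significance filter.

#' Filter clock candidates on circadian parameters
#'
#' Applies the conjunctive core-clock criterion: absolute amplitude
#' strictly greater than `amp_min`, fold-change strictly greater than
#' `fc_min`, and JTK p-value at most `p_max`. A candidate missing any of
#' the three values fails that criterion (e.g. a fold-change undefined
#' because the profile reaches zero, or a p-value absent because the gene
#' was removed by the expression filter).
#'
#' @param candidates Tibble with `amplitude`, `fold_change`, and `jtk_p`
#'   columns (missing values allowed).
#' @param amp_min Minimum absolute amplitude (exclusive), FPKM.
#' @param fc_min Minimum fold-change (exclusive).
#' @param p_max Maximum JTK p-value (inclusive).
#' @return `candidates` with a logical `passes` column appended.
#' @examples
#' clock_filter(tibble::tibble(amplitude = c(42.12, 8.30),
#'                             fold_change = c(10.95, 1.97),
#'                             jtk_p = c(1.06e-5, 1.65e-2)))
#' @export
clock_filter <- function(candidates, amp_min = 10, fc_min = 2, p_max = 0.05) {
  ok <- function(x) !is.na(x) & x
  candidates$passes <- ok(candidates$amplitude > amp_min) &
    ok(candidates$fold_change > fc_min) &
    ok(candidates$jtk_p <= p_max)
  candidates
}

#' Profile core-clock candidate genes
#'
#' Builds a per-candidate report: circadian parameters computed from the
#' expression matrix, normalized rank and JTK p looked up in the detection
#' records, and the pass/fail call from [clock_filter()]. Candidates absent
#' from the matrix (or from the records, e.g. removed by the low-expression
#' filter before detection) carry missing values for the affected columns
#' and therefore fail the filter.
#'
#' @param expr A diel expression tibble (before any low-expression
#'   filtering, so removed candidates can still be parameterised when
#'   present).
#' @param records Detection records with `gene_id`, `normalized_rank`,
#'   `jtk_p` (e.g. [tidy()] of a [detect_rhythmic()] result).
#' @param candidate_map Tibble with `gene_name` and `gene_id` columns.
#' @inheritParams clock_filter
#' @return A tibble with one row per candidate: `gene_name`, `gene_id`,
#'   `normalized_rank`, `mean_fpkm`, `amplitude`, `fold_change`, `jtk_p`,
#'   `passes`.
#' @export
profile_clock_genes <- function(expr, records, candidate_map,
                                amp_min = 10, fc_min = 2, p_max = 0.05) {
  if (is.null(candidate_map) || nrow(candidate_map) == 0L) {
    rlang::abort("`candidate_map` must list at least one candidate.")
  }
  check_expr(expr)
  grid <- diel_grid(expr)
  m <- expr_values(expr)
  params <- purrr::map_dfr(candidate_map$gene_id, function(id) {
    i <- match(id, rownames(m))
    if (is.na(i)) {
      tibble::tibble(mean_fpkm = NA_real_, amplitude = NA_real_,
                     fold_change = NA_real_, phase_call_h = NA_real_)
    } else {
      circadian_params(m[i, ], grid)
    }
  })
  rec <- records[match(candidate_map$gene_id, records$gene_id), ]
  out <- tibble::tibble(
    gene_name = candidate_map$gene_name,
    gene_id = candidate_map$gene_id,
    normalized_rank = rec$normalized_rank,
    mean_fpkm = params$mean_fpkm,
    amplitude = params$amplitude,
    fold_change = params$fold_change,
    jtk_p = rec$jtk_p
  )
  clock_filter(out, amp_min = amp_min, fc_min = fc_min, p_max = p_max)
}

extdata_tsv <- function(file) {
  path <- system.file("extdata", file, package = "dielcompare",
                      mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE, na = "NA")
}

#' Curated circadian parameters of K. fedtschenkoi core-clock orthologs
#'
#' Reference table of Kalanchoe fedtschenkoi orthologs of the Arabidopsis
#' core circadian clock genes, with their reported consensus normalized
#' rank, mean FPKM, absolute amplitude, fold-change, and JTK-CYCLE p-value
#' from a diel time course. Rows with missing rank and p correspond to
#' candidates removed by the max-FPKM expression filter before detection.
#'
#' @return A tibble with columns `gene_name`, `gene_id`,
#'   `normalized_rank`, `mean_fpkm`, `amplitude`, `fold_change`, `jtk_p`.
#' @export
clock_ortholog_params <- function() {
  extdata_tsv("kfed_clock_orthologs.tsv")
}

#' Curated rhythmic transcription-factor ortholog pairs with phase calls
#'
#' Reference table of one-to-one rhythmic transcription-factor ortholog
#' pairs between Kalanchoe fedtschenkoi and Arabidopsis thaliana: each
#' species' gene locus and phase call (hours after first light), the
#' Arabidopsis functional description, and the reported circular phase
#' shift between the pair.
#'
#' @return A tibble with columns `kfed_id`, `kfed_phase_h`, `ath_id`,
#'   `ath_phase_h`, `description`, `reported_shift_h`.
#' @export
tf_ortholog_pairs <- function() {
  extdata_tsv("tf_ortholog_phase_calls.tsv")
}
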