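# Consensus rank aggregation across periodicity algorithms: rank per
# algorithm, sum, re-rank, then gate on the JTK p-value.

#' Rank genes per algorithm
#'
#' Adds a rank column per algorithm score (rank 1 = most rhythmic =
#' smallest p or score) with average ranks on ties. Genes missing a score
#' are ranked last for that algorithm and reported in a message.
#'
#' @param scores A tibble as returned by [rhythm_scores()], or any tibble
#'   with `gene_id` and the named score columns.
#' @param algorithms Named character vector mapping an algorithm label to
#'   its score column; ranks appear as `rank_<label>`.
#' @return `scores` with one `rank_<label>` column per algorithm.
#' @export
rank_by_algorithm <- function(scores,
                              algorithms = c(jtk = "jtk_p", ls = "ls_p",
                                             dl = "dl_score")) {
  missing_cols <- setdiff(unname(algorithms), names(scores))
  if (length(missing_cols) > 0L) {
    rlang::abort(sprintf("score column(s) not found: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  out <- scores
  for (lab in names(algorithms)) {
    x <- scores[[algorithms[[lab]]]]
    if (anyNA(x)) {
      rlang::inform(sprintf(
        "%d gene(s) missing a %s score are ranked last for that algorithm.",
        sum(is.na(x)), lab
      ))
    }
    r <- rank(x, ties.method = "average", na.last = "keep")
    r[is.na(r)] <- length(x)
    out[[paste0("rank_", lab)]] <- r
  }
  out
}

#' Aggregate per-algorithm ranks into a consensus ordering
#'
#' Sums the per-algorithm ranks into a cumulative rank and re-ranks genes
#' by it; the normalized rank is the resulting ordinal position (1 = most
#' rhythmic by consensus), with ties broken by smaller JTK p-value and then
#' lexicographic gene ID so the ordering is deterministic.
#'
#' @param ranked A tibble from [rank_by_algorithm()] (must hold `gene_id`,
#'   `jtk_p` and the `rank_*` columns).
#' @return `ranked` with `cumulative_rank` and `normalized_rank` columns,
#'   sorted by `normalized_rank`.
#' @export
aggregate_ranks <- function(ranked) {
  rank_cols <- grep("^rank_", names(ranked), value = TRUE)
  if (length(rank_cols) < 2L) {
    rlang::abort("at least 2 per-algorithm rank columns are required.")
  }
  out <- ranked
  out$cumulative_rank <- rowSums(out[, rank_cols, drop = FALSE])
  ord <- order(out$cumulative_rank, out$jtk_p, out$gene_id)
  out <- out[ord, , drop = FALSE]
  out$normalized_rank <- seq_len(nrow(out))
  out
}

#' Select the high-confidence rhythmic gene set
#'
#' A gene is selected when its normalized rank is at most `cutoff_n` and
#' its JTK p-value is at most `p_gate` (both bounds inclusive). The cutoff
#' is a required study choice, typically fixed after inspecting cohorts of
#' the consensus ordering (see [cohort_chunks()]).
#'
#' @param records A tibble from [aggregate_ranks()].
#' @param cutoff_n Normalized-rank cutoff (at most the number of genes).
#' @param p_gate JTK p-value gate.
#' @return Character vector of selected gene IDs, in consensus order.
#' @export
select_rhythmic <- function(records, cutoff_n, p_gate = 0.06) {
  if (cutoff_n > nrow(records)) {
    rlang::abort("`cutoff_n` exceeds the number of genes.")
  }
  keep <- records$normalized_rank <= cutoff_n & records$jtk_p <= p_gate
  records$gene_id[keep][order(records$normalized_rank[keep])]
}

#' Chunk z-scored profiles in consensus order for visual inspection
#'
#' Splits the genes, ordered by normalized rank, into cohorts of
#' `cohort_size` z-scored profiles. Plotting successive cohorts (e.g. with
#' [plot_expression_heatmap()]) shows where rhythmicity visibly decays,
#' which is how the rank cutoff is chosen.
#'
#' @param records A tibble from [aggregate_ranks()].
#' @param expr The diel expression tibble the records were scored from.
#' @param cohort_size Genes per cohort.
#' @return A list of diel expression tibbles of z-scores, in rank order.
#' @export
cohort_chunks <- function(records, expr, cohort_size = 500) {
  check_expr(expr)
  ord <- records$gene_id[order(records$normalized_rank)]
  z <- suppressWarnings(zscore_expression(expr))
  z <- z[match(ord, z$gene_id), , drop = FALSE]
  idx <- ceiling(seq_len(nrow(z)) / cohort_size)
  lapply(split(seq_len(nrow(z)), idx), function(i) z[i, , drop = FALSE])
}

#' Detect rhythmic genes in a diel expression matrix
#'
#' End-to-end detection: scores every gene with the three periodicity
#' algorithms ([rhythm_scores()]), aggregates the per-algorithm rankings
#' into a consensus ordering, and selects genes with normalized rank at
#' most `cutoff_n` and JTK p at most `p_gate`.
#'
#' @inheritParams rhythm_scores
#' @inheritParams select_rhythmic
#' @return A `rhythm_detection` object; see [tidy.rhythm_detection()] for
#'   the per-gene records and [glance.rhythm_detection()] for the summary.
#' @examples
#' sim <- simulate_diel_matrix(60, 0.5, noise_frac = 0.1, seed = 1)
#' det <- detect_rhythmic(sim$expr, cutoff_n = 30, n_perm = 200, seed = 2)
#' glance(det)
#' @export
detect_rhythmic <- function(expr, cutoff_n, p_gate = 0.06, period = 24,
                            n_perm = 1000, seed = NULL) {
  check_expr(expr)
  records <- rhythm_scores(expr, period = period, n_perm = n_perm, seed = seed) |>
    rank_by_algorithm() |>
    aggregate_ranks()
  selected <- select_rhythmic(records, cutoff_n = cutoff_n, p_gate = p_gate)
  records$is_rhythmic <- records$gene_id %in% selected
  structure(
    list(
      records = records, rhythmic = selected, expr = expr,
      params = list(cutoff_n = cutoff_n, p_gate = p_gate, period = period,
                    n_perm = n_perm, seed = seed),
      species = expr_species(expr)
    ),
    class = "rhythm_detection"
  )
}

#' @export
print.rhythm_detection <- function(x, ...) {
  cat(sprintf(
    "<rhythm_detection> %d genes, %d rhythmic (normalized rank <= %d, JTK p <= %g)\n",
    nrow(x$records), length(x$rhythmic), x$params$cutoff_n, x$params$p_gate
  ))
  invisible(x)
}

#' Tidy a rhythm detection
#'
#' @param x A `rhythm_detection` object.
#' @param ... Unused.
#' @return The per-gene record tibble: algorithm scores and ranks,
#'   cumulative and normalized ranks, circadian parameters, and the
#'   `is_rhythmic` flag.
#' @method tidy rhythm_detection
#' @export
tidy.rhythm_detection <- function(x, ...) x$records

#' Summarise a rhythm detection
#'
#' @inheritParams tidy.rhythm_detection
#' @return A one-row tibble: gene counts, cutoffs, and test period.
#' @method glance rhythm_detection
#' @export
glance.rhythm_detection <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$records), n_rhythmic = length(x$rhythmic),
    cutoff_n = x$params$cutoff_n, p_gate = x$params$p_gate,
    period = x$params$period, species = x$species
  )
}

#' Phase-ordered heat map of the selected rhythmic genes
#'
#' @param object A `rhythm_detection` object.
#' @param ... Unused.
#' @return A ggplot: z-scored profiles of the selected genes ordered by
#'   phase call, the classic diagonal wave of diel transcriptomes.
#' @method autoplot rhythm_detection
#' @export
autoplot.rhythm_detection <- function(object, ...) {
  rec <- object$records
  sel <- rec[rec$is_rhythmic, ]
  ord <- sel$gene_id[order(sel$phase_call_h, sel$normalized_rank)]
  expr <- object$expr
  plot_expression_heatmap(expr[match(ord, expr$gene_id), , drop = FALSE],
                          order_by = "none")
}
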