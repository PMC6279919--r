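# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: permutations are enumerated outright, Spearman
# edges are recomputed pair by pair, and the sinusoid fit is an lm().

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) cbind(k, p + (p >= k))))
}

# Brute-force JTK p-value: min over lagged-cosine references of the exact
# permutation tail of the concordance statistic, Bonferroni-corrected by
# the number of distinct reference orderings. Enumerates all n! orderings.
brute_jtk_p <- function(y, grid, period = 24) {
  n <- length(y)
  pairs <- t(utils::combn(n, 2))
  refs <- lapply(grid, function(l) round(cos(2 * pi * (grid - l) / period), 9))
  stat <- function(v, r) {
    sy <- sign(v[pairs[, 1]] - v[pairs[, 2]])
    sr <- sign(r[pairs[, 1]] - r[pairs[, 2]])
    comp <- sr != 0
    sum((sy * sr)[comp] > 0) + 0.5 * sum(sy[comp] == 0)
  }
  P <- all_perms(n)
  p_lag <- vapply(refs, function(r) {
    obs <- stat(y, r)
    null <- apply(P, 1L, function(ix) stat(y[ix], r))
    mean(null >= obs - 1e-9)
  }, numeric(1))
  n_ord <- nrow(unique(do.call(rbind, lapply(refs, rank))))
  min(1, n_ord * min(p_lag))
}

# Least-squares sinusoid regression: Lomb-Scargle power should equal the
# explained variance fraction times (N - 1) / 2 on any profile sampled on
# a uniform complete cycle.
sinefit_power <- function(y, grid, period = 24) {
  w <- 2 * pi / period
  fit <- stats::lm(y ~ cos(w * grid) + sin(w * grid))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  r2 * (length(y) - 1) / 2
}

# All-pairs Spearman edges, one cor() call per pair.
brute_edges <- function(expr, rho_min) {
  m <- as.matrix(expr[, -1])
  ids <- expr$gene_id
  out <- list()
  for (i in seq_len(nrow(m) - 1L)) {
    for (j in (i + 1L):nrow(m)) {
      rho <- suppressWarnings(stats::cor(m[i, ], m[j, ], method = "spearman"))
      if (!is.na(rho) && rho >= rho_min) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = ids[i], gene_b = ids[j], rho = rho
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      rho = numeric()))
  }
  do.call(rbind, out)
}

rank_auc <- function(score, truth) {
  r <- rank(score)
  w <- sum(r[!truth]) - sum(!truth) * (sum(!truth) + 1) / 2
  w / (sum(truth) * sum(!truth))
}

expect_tbl_equal <- function(a, b, tol = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
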