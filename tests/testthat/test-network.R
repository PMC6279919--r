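grid12 <- seq(2, 24, by = 2)

as_expr <- function(m, ids) {
  out <- tibble::tibble(gene_id = ids)
  for (j in seq_len(ncol(m))) out[[as.character(grid12[j])]] <- m[, j]
  out
}

test_that("edges follow the signed Spearman cutoff", {
  set.seed(15)
  base <- rnorm(12)  # no ties, so affine copies are rank-identical
  expr <- as_expr(rbind(base, 3 * base + 2, -base, rnorm(12)),
                  c("up1", "up2", "anti", "noise"))
  net <- build_gcn(expr, rho_min = 0.8)
  expect_equal(nrow(net$nodes), 4)
  ed <- tidy(net)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$gene_a, ed$gene_b), c("up1", "up2"))
  expect_equal(ed$rho, 1)
  # the perfectly anti-correlated pair is excluded by the signed cutoff
  expect_false(any(ed$gene_a == "anti" | ed$gene_b == "anti"))
})

test_that("4-gene networks match the brute-force all-pairs oracle", {
  set.seed(31)
  for (rep in 1:5) {
    expr <- as_expr(matrix(rnorm(48), 4), sprintf("g%d", 1:4))
    for (cutoff in c(-0.5, 0.2, 0.8)) {
      net <- build_gcn(expr, rho_min = cutoff)
      want <- brute_edges(expr, cutoff)
      got <- tidy(net)[order(tidy(net)$gene_a, tidy(net)$gene_b), ]
      want <- want[order(want$gene_a, want$gene_b), ]
      expect_equal(as.data.frame(got), as.data.frame(want),
                   ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("blocked computation agrees with a single block", {
  sim <- simulate_diel_matrix(60, 1, noise_frac = 0.3, seed = 17)
  a <- build_gcn(sim$expr, rho_min = 0.7, block_size = 7L)
  b <- build_gcn(sim$expr, rho_min = 0.7, block_size = 1000L)
  key <- function(net) {
    ed <- tidy(net)
    ed[order(ed$gene_a, ed$gene_b), ]
  }
  expect_equal(as.data.frame(key(a)), as.data.frame(key(b)), tolerance = 1e-12)
})

test_that("raising the cutoff never adds edges; same-phase cosines form cliques", {
  sim <- simulate_diel_matrix(12, 1, noise_frac = 0, peaked_frac = 0,
                              phases = rep(c(8, 20), 6), seed = 23)
  lo <- build_gcn(sim$expr, rho_min = 0.6)
  hi <- build_gcn(sim$expr, rho_min = 0.9)
  pair_key <- function(net) paste(tidy(net)$gene_a, tidy(net)$gene_b)
  expect_true(all(pair_key(hi) %in% pair_key(lo)))

  # noiseless rectified cosines sharing a phase form cliques at the 0.8
  # cutoff: every same-phase pair is an edge
  ph <- setNames(sim$truth$true_phase_h, sim$truth$gene_id)
  ed <- tidy(build_gcn(sim$expr, rho_min = 0.8))
  same <- ph[ed$gene_a] == ph[ed$gene_b]
  n_per_phase <- table(sim$truth$true_phase_h)
  expect_equal(sum(same), sum(choose(n_per_phase, 2)))
})

test_that("constant genes stay as isolated nodes with a warning", {
  expr <- as_expr(rbind(sin(2 * pi * grid12 / 24), rep(3, 12)),
                  c("osc", "flat"))
  expect_warning(net <- build_gcn(expr), "constant")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(tidy(net)), 0)
  expect_error(build_gcn(expr, genes = c("osc", "missing")), "not in the matrix")
})

test_that("networks round-trip through edge-list and GraphML exports", {
  sim <- simulate_diel_matrix(15, 1, noise_frac = 0.2, seed = 29)
  net <- build_gcn(sim$expr, rho_min = 0.7)
  expect_gt(nrow(tidy(net)), 0)

  for (fmt in c("edge_list", "graphml")) {
    path <- withr::local_tempfile(fileext = if (fmt == "graphml") ".graphml" else ".tsv")
    export_network(net, path, format = fmt)
    back <- read_network(path, format = fmt, rho_min = net$rho_min)
    expect_setequal(back$nodes$gene_id, net$nodes$gene_id)
    expect_equal(
      back$nodes$phase_call_h[match(net$nodes$gene_id, back$nodes$gene_id)],
      net$nodes$phase_call_h
    )
    key <- function(ed) {
      a <- pmin(ed$gene_a, ed$gene_b); b <- pmax(ed$gene_a, ed$gene_b)
      ord <- order(a, b)
      data.frame(a = a[ord], b = b[ord], rho = round(ed$rho[ord], 9))
    }
    expect_equal(key(tidy(back)), key(tidy(net)), tolerance = 1e-6)
  }
  expect_error(export_network(net, tempfile(), format = "dot"), "should be one of")

  # an empty network still exports and re-imports
  empty <- build_gcn(sim$expr[1:2, ], rho_min = 1.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_network(empty, path)
  back <- read_network(path)
  expect_equal(nrow(tidy(back)), 0)
  expect_equal(nrow(back$nodes), 2)
  expect_s3_class(autoplot(net), "ggplot")
})
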