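grid12 <- seq(2, 24, by = 2)

test_that("simulated matrices honour the requested composition and seed", {
  sim <- simulate_diel_matrix(1000, 0.3, seed = 42)
  expect_equal(sum(sim$truth$is_rhythmic), 300)
  expect_equal(nrow(sim$expr), 1000)
  expect_equal(diel_grid(sim$expr), grid12)
  # same spec, same seed: identical draws; different seed: different values
  again <- simulate_diel_matrix(1000, 0.3, seed = 42)
  expect_equal(sim, again)
  other <- simulate_diel_matrix(1000, 0.3, seed = 43)
  expect_false(isTRUE(all.equal(sim$expr, other$expr)))
  # arrhythmic truth rows are flat by construction
  expect_true(all(sim$truth$true_amplitude[!sim$truth$is_rhythmic] == 0))
  expect_true(all(sim$truth$true_phase_h[sim$truth$is_rhythmic] %in% grid12))
})

test_that("noiseless profiles peak exactly at the true phase", {
  sim <- simulate_diel_matrix(200, 1, noise_frac = 0, seed = 8)
  m <- as.matrix(sim$expr[, -1])
  called <- apply(m, 1L, phase_call, grid = grid12)
  expect_equal(unname(called), sim$truth$true_phase_h)
})

test_that("degenerate generator inputs are rejected", {
  expect_error(simulate_diel_matrix(10, 0.5, grid = c(2, 4, 8, 16, 20, 24)),
               "uniform")
  expect_error(simulate_diel_matrix(10, 0.5, grid = seq(2, 12, 2)), "period")
  expect_error(simulate_diel_matrix(10, 1.5), "frac_rhythmic")
})

test_that("ortholog scenarios round-trip the requested type counts", {
  counts <- c(T1 = 5, T2 = 3, T3 = 2, T4 = 4, T5 = 6)
  classify_scenario <- function(sc) {
    cl <- classify_types(
      sc$groups,
      rhythmic_a = sc$truth_a$gene_id[sc$truth_a$is_rhythmic],
      rhythmic_b = sc$truth_b$gene_id[sc$truth_b$is_rhythmic],
      all_genes_a = sc$truth_a$gene_id,
      all_genes_b = sc$truth_b$gene_id
    )
    table(factor(cl$group_types$type,
                 levels = paste0("Type", 1:5)))
  }
  sc <- simulate_ortholog_scenario(counts, seed = 1)
  got <- classify_scenario(sc)
  expect_equal(unname(as.vector(got)), unname(counts[paste0("T", 1:5)]))

  # Type 4 groups contain no species-B genes at all
  cl <- classify_types(sc$groups,
                       sc$truth_a$gene_id[sc$truth_a$is_rhythmic],
                       sc$truth_b$gene_id[sc$truth_b$is_rhythmic],
                       sc$truth_a$gene_id, sc$truth_b$gene_id)
  t4 <- cl$group_types[cl$group_types$type == "Type4", ]
  expect_true(all(t4$n_b == 0))

  # counts survive any seed while the values change
  for (seed in 2:11) {
    sc_i <- simulate_ortholog_scenario(counts, seed = seed)
    expect_equal(unname(as.vector(classify_scenario(sc_i))),
                 unname(counts[paste0("T", 1:5)]))
  }
  sc2 <- simulate_ortholog_scenario(counts, seed = 2)
  expect_false(isTRUE(all.equal(sc$expr_a, sc2$expr_a)))
})

test_that("scenario padding and extra rhythmic genes preserve the counts", {
  counts <- c(T1 = 3, T2 = 2, T3 = 2, T4 = 1, T5 = 1)
  sc <- simulate_ortholog_scenario(counts, n_genes_per_species = 40,
                                   frac_rhythmic = 0.5, seed = 5)
  expect_equal(nrow(sc$truth_a), 40)
  expect_equal(sum(sc$truth_a$is_rhythmic), 20)
  expect_equal(sum(sc$truth_b$is_rhythmic), 20)
  cl <- classify_types(sc$groups,
                       sc$truth_a$gene_id[sc$truth_a$is_rhythmic],
                       sc$truth_b$gene_id[sc$truth_b$is_rhythmic],
                       sc$truth_a$gene_id, sc$truth_b$gene_id)
  got <- table(factor(cl$group_types$type, levels = paste0("Type", 1:5)))
  expect_equal(unname(as.vector(got)), unname(counts[paste0("T", 1:5)]))

  # infeasible requests are refused
  expect_error(simulate_ortholog_scenario(counts, n_genes_per_species = 4),
               "too small")
  expect_error(
    simulate_ortholog_scenario(counts, n_genes_per_species = 40,
                               frac_rhythmic = 0.05),
    "fewer rhythmic"
  )
})

test_that("ortholog groups round-trip through the two-column text format", {
  sc <- simulate_ortholog_scenario(c(T1 = 2, T2 = 1, T3 = 1, T4 = 1, T5 = 1),
                                   seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ortholog_groups(sc$groups, path)
  back <- read_ortholog_groups(path)
  expect_equal(as.data.frame(back), as.data.frame(sc$groups))
})
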