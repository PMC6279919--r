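toy_universe <- function() {
  list(
    groups = tibble::tibble(
      group_id = c("og1", "og1", "og2", "og2", "og3", "og3", "og4", "og5",
                   "og6", "og6"),
      gene_id = c("a1", "k1", "a2", "k2", "a3", "k3", "a4", "k5",
                  "a6", "k6")
    ),
    rhythmic_a = c("a1", "a2", "a4", "a7"),
    rhythmic_b = c("k1", "k3", "k5", "k8"),
    all_a = sprintf("a%d", 1:7),
    all_b = sprintf("k%d", 1:8)
  )
}

test_that("type classification follows the five definitions", {
  u <- toy_universe()
  cl <- classify_types(u$groups, u$rhythmic_a, u$rhythmic_b, u$all_a, u$all_b)
  types <- setNames(cl$group_types$type, cl$group_types$group_id)
  expect_equal(unname(types[c("og1", "og2", "og3", "og4", "og5")]),
               c("Type1", "Type2", "Type3", "Type4", "Type5"))
  # og6 has no rhythmic member: untyped
  expect_true(is.na(types[["og6"]]))
  # ungrouped rhythmic genes become Type 4/5 singletons by species
  gt <- cl$gene_types
  expect_equal(gt$type[gt$gene_id == "a7"], "Type4")
  expect_equal(gt$type[gt$gene_id == "k8"], "Type5")
  expect_true(all(is.na(gt$group_id[gt$gene_id %in% c("a7", "k8")])))
  # every rhythmic gene is typed exactly once
  expect_setequal(gt$gene_id, c(u$rhythmic_a, u$rhythmic_b))
  expect_equal(anyDuplicated(gt$gene_id), 0L)
})

test_that("classification validates its inputs", {
  u <- toy_universe()
  dup <- dplyr::bind_rows(u$groups,
                          tibble::tibble(group_id = "og9", gene_id = "a1"))
  expect_error(classify_types(dup, u$rhythmic_a, u$rhythmic_b,
                              u$all_a, u$all_b), "more than one group")
  expect_error(classify_types(u$groups, c(u$rhythmic_a, "zz"), u$rhythmic_b,
                              u$all_a, u$all_b), "subsets")
  expect_error(classify_types(u$groups, u$rhythmic_a, u$rhythmic_b,
                              u$all_a, c(u$all_b, "a1")), "overlap")
})

test_that("refinement keeps one-to-one Type 1 groups and pure Type 2/3 splits", {
  groups <- tibble::tibble(
    group_id = c("p1", "p1", "p2", "p2", "p2", "p3", "p3", "p3", "p3",
                 "q1", "q1", "q2", "q2", "q2"),
    gene_id = c("a1", "k1", "a2", "a3", "k2", "a4", "a5", "a6", "k3",
                "a7", "k4", "a8", "a9", "k5")
  )
  rhythmic_a <- c("a1", "a2", "a3", "a4", "a7", "a8")
  rhythmic_b <- c("k1", "k2", "k3")
  all_a <- sprintf("a%d", 1:9)
  all_b <- sprintf("k%d", 1:5)
  cl <- classify_types(groups, rhythmic_a, rhythmic_b, all_a, all_b)

  # p1: 1+1 rhythmic; p2: two rhythmic A genes; p3: 1 rhythmic + 2
  # arrhythmic A paralogs (still refined: only rhythmic genes count)
  ref1 <- refine_type1(cl$group_types)
  expect_setequal(ref1$group_id, c("p1", "p3"))
  expect_true(all(ref1$group_id %in%
                    cl$group_types$group_id[cl$group_types$type == "Type1"]))

  # q1 is pure (a7 rhythmic, k4 arrhythmic); q2 carries an arrhythmic A gene
  ref2 <- refine_pure(cl$group_types, "Type2")
  expect_equal(ref2$group_id, "q1")
  expect_true(all(ref2$group_id %in%
                    cl$group_types$group_id[cl$group_types$type == "Type2"]))
})

test_that("phase shifts reproduce the printed ortholog-pair examples", {
  expect_equal(phase_shift(2, 20), 6)
  expect_equal(phase_shift(4, 16), 12)
  expect_equal(phase_shift(8, 8), 0)
  expect_equal(phase_shift(22, 8), 10)
  expect_equal(phase_shift(6, 24), 6)
  expect_equal(phase_shift(10, 4), 6)
})

test_that("phase shift is a circular semi-metric on the 24-h clock", {
  phases <- seq(2, 24, by = 2)
  for (a in phases) {
    for (b in phases) {
      s <- phase_shift(a, b)
      expect_equal(s, phase_shift(b, a))
      expect_gte(s, 0)
      expect_lte(s, 12)
      if (a == b) expect_equal(s, 0) else expect_gt(s, 0)
    }
  }
})

test_that("synchrony is an inclusive 4-h boundary partition", {
  expect_true(classify_sync(0))
  expect_true(classify_sync(4))
  expect_false(classify_sync(6))
  shifts <- c(0, 2, 4, 6, 8, 10, 12)
  expect_equal(classify_sync(shifts), shifts <= 4)
})

test_that("phase_pairs pairs single rhythmic genes across species", {
  sc <- simulate_ortholog_scenario(c(T1 = 6, T2 = 2, T3 = 2, T4 = 1, T5 = 1),
                                   noise_frac = 0, seed = 13)
  cl <- classify_types(sc$groups,
                       sc$truth_a$gene_id[sc$truth_a$is_rhythmic],
                       sc$truth_b$gene_id[sc$truth_b$is_rhythmic],
                       sc$truth_a$gene_id, sc$truth_b$gene_id)
  phases <- dplyr::bind_rows(
    tibble::tibble(gene_id = sc$truth_a$gene_id,
                   phase_call_h = apply(as.matrix(sc$expr_a[, -1]), 1,
                                        phase_call, grid = diel_grid(sc$expr_a))),
    tibble::tibble(gene_id = sc$truth_b$gene_id,
                   phase_call_h = apply(as.matrix(sc$expr_b[, -1]), 1,
                                        phase_call, grid = diel_grid(sc$expr_b)))
  )
  pp <- phase_pairs(cl, phases)
  expect_equal(nrow(pp), nrow(refine_type1(cl$group_types)))
  # noiseless: observed pair shifts equal the truth-phase shifts
  truth_phase <- setNames(c(sc$truth_a$true_phase_h, sc$truth_b$true_phase_h),
                          c(sc$truth_a$gene_id, sc$truth_b$gene_id))
  expect_equal(pp$shift_h,
               phase_shift(truth_phase[pp$gene_a], truth_phase[pp$gene_b]),
               ignore_attr = TRUE)
  expect_equal(pp$synchronized, pp$shift_h <= 4)
})

test_that("taxon presence categories are exhaustive and exclusive", {
  hits <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g2"),
    taxon = c("cam1", "c3_1", "cam1", "c3_1", "c3_2", "cam2")
  )
  res <- taxon_presence_classify(
    hits, genes = c("g1", "g2", "g3", "g4"),
    cam_taxa = c("cam1", "cam2"), noncam_taxa = c("c3_1", "c3_2"),
    self_taxon = "kfed"
  )
  expect_equal(setNames(res$category, res$gene_id),
               c(g1 = "shared", g2 = "CAM_only", g3 = "nonCAM_only",
                 g4 = "species_specific"))
  expect_error(
    taxon_presence_classify(hits, "g1", "cam1", "c3_1", self_taxon = "cam1"),
    "exclude"
  )
  expect_error(
    taxon_presence_classify(hits, "g1", "cam1", c("c3_1", "c3_2"), "kfed"),
    "neither partition"
  )
})
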