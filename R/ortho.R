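# Cross-species comparison of rhythmic gene sets through ortholog groups:
# five conservation types, refinement, circular phase shifts, synchrony,
# and taxon-presence categories.

#' Classify ortholog groups into the five rhythmicity-conservation types
#'
#' Given ortholog groups and each species' rhythmic gene set, assigns:
#' Type 1 to groups with at least one rhythmic gene in each species;
#' Type 2 to groups with a rhythmic species-A gene whose species-B members
#' are present but all arrhythmic; Type 3 to the mirror; Type 4 to groups
#' with a rhythmic species-A gene and no species-B members at all; Type 5
#' to the mirror. Groups without any rhythmic gene are left untyped.
#' Rhythmic genes that belong to no group are typed 4/5 by species in the
#' per-gene table (arrhythmic singletons are ignored). A gene's species is
#' determined by which universe contains it.
#'
#' @param groups Tibble with `group_id`, `gene_id` (a gene may appear in at
#'   most one group).
#' @param rhythmic_a,rhythmic_b Rhythmic gene IDs per species (subsets of
#'   the universes).
#' @param all_genes_a,all_genes_b The species' gene universes (disjoint).
#' @return A list with `group_types` (one row per group: `group_id`,
#'   `type`, member and rhythmic-member counts per species) and
#'   `gene_types` (one row per rhythmic gene: `gene_id`, `species`,
#'   `group_id`, `type`).
#' @export
classify_types <- function(groups, rhythmic_a, rhythmic_b,
                           all_genes_a, all_genes_b) {
  overlap <- intersect(all_genes_a, all_genes_b)
  if (length(overlap) > 0L) {
    rlang::abort("gene universes overlap; IDs must identify one species.")
  }
  if (!all(rhythmic_a %in% all_genes_a) || !all(rhythmic_b %in% all_genes_b)) {
    rlang::abort("rhythmic sets must be subsets of their gene universes.")
  }
  if (anyDuplicated(groups$gene_id)) {
    dup <- unique(groups$gene_id[duplicated(groups$gene_id)])
    rlang::abort(sprintf("gene(s) in more than one group: %s",
                         paste(utils::head(dup, 5L), collapse = ", ")))
  }

  g <- dplyr::mutate(
    groups,
    species = dplyr::case_when(
      .data$gene_id %in% all_genes_a ~ "A",
      .data$gene_id %in% all_genes_b ~ "B",
      TRUE ~ NA_character_
    ),
    rhythmic = .data$gene_id %in% c(rhythmic_a, rhythmic_b)
  )
  if (anyNA(g$species)) {
    rlang::abort("some grouped genes belong to neither gene universe.")
  }

  group_types <- g |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      n_a = sum(.data$species == "A"),
      n_b = sum(.data$species == "B"),
      n_rhythmic_a = sum(.data$species == "A" & .data$rhythmic),
      n_rhythmic_b = sum(.data$species == "B" & .data$rhythmic),
      .groups = "drop"
    ) |>
    dplyr::mutate(type = dplyr::case_when(
      .data$n_rhythmic_a > 0 & .data$n_rhythmic_b > 0 ~ "Type1",
      .data$n_rhythmic_a > 0 & .data$n_b > 0 ~ "Type2",
      .data$n_rhythmic_b > 0 & .data$n_a > 0 ~ "Type3",
      .data$n_rhythmic_a > 0 ~ "Type4",
      .data$n_rhythmic_b > 0 ~ "Type5",
      TRUE ~ NA_character_
    )) |>
    dplyr::relocate("group_id", "type")

  grouped <- dplyr::left_join(
    dplyr::filter(g, .data$rhythmic),
    group_types[, c("group_id", "type")],
    by = "group_id"
  )[, c("gene_id", "species", "group_id", "type")]

  loose <- setdiff(c(rhythmic_a, rhythmic_b), groups$gene_id)
  if (length(loose) > 0L) {
    grouped <- dplyr::bind_rows(grouped, tibble::tibble(
      gene_id = loose,
      species = ifelse(loose %in% all_genes_a, "A", "B"),
      group_id = NA_character_,
      type = ifelse(loose %in% all_genes_a, "Type4", "Type5")
    ))
  }

  list(group_types = group_types,
       gene_types = dplyr::arrange(grouped, .data$gene_id))
}

#' Refine Type 1 groups to single-profile pairs
#'
#' Keeps Type 1 groups with exactly one rhythmic gene in each species, the
#' one-to-one restriction under which a cross-species phase comparison is
#' unambiguous. Arrhythmic paralogs in the group are not counted.
#'
#' @param group_types The `group_types` tibble from [classify_types()].
#' @return The subset of Type 1 rows with one rhythmic gene per species.
#' @export
refine_type1 <- function(group_types) {
  dplyr::filter(
    group_types,
    .data$type == "Type1", .data$n_rhythmic_a == 1, .data$n_rhythmic_b == 1
  )
}

#' Refine Type 2/3 groups to pure rhythmic/arrhythmic splits
#'
#' Keeps groups of the stated type in which every gene of the rhythmic-side
#' species is rhythmic and every gene of the other species is arrhythmic.
#'
#' @inheritParams refine_type1
#' @param type `"Type2"` (rhythmic side = species A) or `"Type3"`.
#' @return The refined subset of rows.
#' @export
refine_pure <- function(group_types, type = c("Type2", "Type3")) {
  type <- match.arg(type)
  gt <- dplyr::filter(group_types, .data$type == !!type)
  if (type == "Type2") {
    dplyr::filter(gt, .data$n_rhythmic_a == .data$n_a)
  } else {
    dplyr::filter(gt, .data$n_rhythmic_b == .data$n_b)
  }
}

#' Circular phase shift between two phase calls
#'
#' The distance between two phase calls on the periodic clock:
#' `min(|a - b|, period - |a - b|)`, in [0, period/2]. Vectorised.
#'
#' @param phase_a_h,phase_b_h Phase calls in hours.
#' @param period Clock period in hours.
#' @return Phase shift(s) in hours.
#' @examples
#' phase_shift(2, 20)  # wraps: 6 h
#' phase_shift(4, 16)  # antiphase: 12 h
#' @export
phase_shift <- function(phase_a_h, phase_b_h, period = 24) {
  d <- abs(phase_a_h - phase_b_h) %% period
  pmin(d, period - d)
}

#' Synchrony call for a phase shift
#'
#' An ortholog pair is synchronized when its phase shift is within
#' `threshold_h` hours (inclusive), unsynchronized otherwise.
#'
#' @param shift_h Phase shift(s) in hours, in [0, period/2].
#' @param threshold_h Synchrony threshold in hours.
#' @return Logical vector.
#' @export
classify_sync <- function(shift_h, threshold_h = 4) {
  shift_h <= threshold_h
}

#' Cross-species phase pairs for refined Type 1 groups
#'
#' For each one-to-one refined Type 1 group, pairs the single rhythmic gene
#' of each species, looks up their phase calls, and computes the circular
#' phase shift and synchrony call.
#'
#' @param classified The list returned by [classify_types()].
#' @param phases Tibble with `gene_id` and `phase_call_h` covering the
#'   rhythmic genes (e.g. from [rhythm_scores()] of both species).
#' @param threshold_h Synchrony threshold in hours.
#' @param period Clock period in hours.
#' @return A tibble with one row per refined group: `group_id`, `gene_a`,
#'   `gene_b`, `phase_a_h`, `phase_b_h`, `shift_h`, `synchronized`.
#' @export
phase_pairs <- function(classified, phases, threshold_h = 4, period = 24) {
  refined <- refine_type1(classified$group_types)
  gt <- dplyr::filter(classified$gene_types, .data$group_id %in% refined$group_id)
  ph <- stats::setNames(phases$phase_call_h, phases$gene_id)
  wide <- gt |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(
      gene_a = .data$gene_id[.data$species == "A"][1],
      gene_b = .data$gene_id[.data$species == "B"][1],
      .groups = "drop"
    )
  missing_ph <- setdiff(c(wide$gene_a, wide$gene_b), names(ph))
  if (length(missing_ph) > 0L) {
    rlang::abort(sprintf("no phase call for gene(s): %s",
                         paste(utils::head(missing_ph, 5L), collapse = ", ")))
  }
  wide |>
    dplyr::mutate(
      phase_a_h = unname(ph[.data$gene_a]),
      phase_b_h = unname(ph[.data$gene_b]),
      shift_h = phase_shift(.data$phase_a_h, .data$phase_b_h, period),
      synchronized = classify_sync(.data$shift_h, threshold_h)
    )
}

#' Categorise genes by homolog presence across CAM and non-CAM taxa
#'
#' For species-restricted rhythmic genes (those with no ortholog in the
#' comparison species), classifies each gene by where homologs were hit in
#' a broader taxon panel: `shared` when both CAM and non-CAM taxa carry a
#' homolog, `CAM_only` / `nonCAM_only` when only one partition does, and
#' `species_specific` when no other taxon does.
#'
#' @param hits Tibble with `gene_id` and `taxon`, one row per homolog hit.
#'   Genes without hits still classify via `genes`.
#' @param genes All gene IDs to classify.
#' @param cam_taxa,noncam_taxa The taxon partition (the query species
#'   itself must not appear in `hits`).
#' @param self_taxon Name of the query species' own taxon.
#' @return Tibble with `gene_id` and `category`.
#' @export
taxon_presence_classify <- function(hits, genes, cam_taxa, noncam_taxa,
                                    self_taxon) {
  if (self_taxon %in% hits$taxon) {
    rlang::abort("`hits` must exclude the query species' own taxon.")
  }
  unknown <- setdiff(unique(hits$taxon), c(cam_taxa, noncam_taxa))
  if (length(unknown) > 0L) {
    rlang::abort(sprintf("taxa in neither partition: %s",
                         paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  per_gene <- hits |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      any_cam = any(.data$taxon %in% cam_taxa),
      any_noncam = any(.data$taxon %in% noncam_taxa),
      .groups = "drop"
    )
  tibble::tibble(gene_id = genes) |>
    dplyr::left_join(per_gene, by = "gene_id") |>
    dplyr::mutate(
      any_cam = dplyr::coalesce(.data$any_cam, FALSE),
      any_noncam = dplyr::coalesce(.data$any_noncam, FALSE),
      category = dplyr::case_when(
        .data$any_cam & .data$any_noncam ~ "shared",
        .data$any_cam ~ "CAM_only",
        .data$any_noncam ~ "nonCAM_only",
        TRUE ~ "species_specific"
      )
    ) |>
    dplyr::select("gene_id", "category")
}
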