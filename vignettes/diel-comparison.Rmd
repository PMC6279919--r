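---
title: "Comparing diel transcriptome rhythmicity across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diel transcriptome rhythmicity across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielcompare)
library(dplyr)
```

## The problem

Plants partition their physiology over the 24-hour light/dark (diel)
cycle, and much of that partitioning is visible as rhythmic transcript
abundance. Comparing *which* genes cycle, and *when* they peak, between a
C3 plant (Arabidopsis thaliana) and an obligate CAM plant (Kalanchoe
fedtschenkoi) asks how circadian output has been rewired as crassulacean
acid metabolism evolved: CAM plants fix CO2 at night and invert their
stomatal rhythms, so orthologous genes may keep, lose, gain, or shift
their rhythmicity between the two photosynthetic types.

`dielcompare` implements that comparison as a reusable pipeline over
single-cycle expression matrices (one FPKM profile per gene, typically 12
samples at 2-h intervals over 24 h):

1.  **Preparation** (`read_expression()`, `filter_low_expression()`,
    `resample_pchip()`, `zscore_expression()`) — parse gene-by-hour TSVs,
    drop genes whose maximum FPKM never reaches 1, and interpolate a
    coarser series (4-h sampling) onto the 2-h grid with shape-preserving
    pchip interpolation so both species share a time scale.
2.  **Rhythmicity detection** (`rhythm_scores()`, `detect_rhythmic()`) —
    score every gene with three periodicity algorithms, aggregate their
    rankings into a consensus, and select a high-confidence rhythmic set.
3.  **Cross-species typing** (`classify_types()`, `refine_type1()`,
    `refine_pure()`) — classify ortholog groups into five
    rhythmicity-conservation types and refine them to unambiguous cases.
4.  **Phase comparison** (`phase_shift()`, `classify_sync()`,
    `phase_pairs()`) — circular phase differences and a 4-h synchrony
    call for one-to-one rhythmic ortholog pairs.
5.  **Networks and clock profiling** (`build_gcn()`,
    `profile_clock_genes()`, `clock_filter()`) — phase-annotated Spearman
    co-expression networks and a circadian-parameter report for core
    clock candidates.

A synthetic two-species generator (`simulate_diel_matrix()`,
`simulate_ortholog_scenario()`) provides ground-truth data so every stage
is testable without any external download.

## The detection model

### JTK-CYCLE (`jtk_cycle()`)

The test asks whether the *ordering* of a profile matches the ordering of
a cosine. For each lag on the sampling grid, the reference
`cos(2*pi*(t - lag)/24)` is discretised to the grid and the number of
concordant pairs `C` between profile and reference is counted — a
Kendall / Jonckheere–Terpstra-type statistic. Pairs the reference ties
(the cosine is symmetric about its peak, so a 12-point grid yields five
tied pairs per lag) are incomparable; pairs tied only in the profile
credit 1/2.

Under the null that all profile orderings are equally likely, `C` follows
the inversion-count distribution of a multiset permutation. Its
generating function is a product of Gaussian binomial coefficients, which
the package accumulates by direct polynomial convolution (the Harding
recursion); the null is therefore *exact*, not asymptotic, and is cached
per tie-group signature. The reported p-value is the smallest per-lag
exact tail, multiplied (Bonferroni) by the number of distinct reference
orderings — 12 on the standard grid — and capped at 1. The reported lag
is the winning reference's hour, with the earliest hour on ties; a
constant profile returns p = 1 with a missing lag. Only the 24-h period
is tested: one cycle of data cannot resolve other periods, so there is no
period scan and no multi-period correction.

The Bonferroni convention follows JTK-CYCLE's and is deliberately
conservative: the per-lag statistics are positively correlated, so the
corrected p overstates the false-positive rate slightly. The test suite
verifies the p-values against full `n!` permutation enumeration for small
grids.

### Lomb–Scargle (`lomb_scargle()`)

The classic variance-normalised periodogram evaluated at the single
target period, with the phase offset `tau` that makes the estimate
equivalent to least-squares sinusoid regression. On a complete uniform
cycle the power equals the regression's explained-variance fraction times
`(N - 1)/2`. The p-value is the single-frequency exponential exceedance
`exp(-power)`; no multi-frequency correction is applied because only one
frequency is examined.

### Periodicity x regulation score (`de_lichtenberg()`)

An empirical two-component score, lower = more rhythmic: the fraction of
random within-gene time-order permutations whose Fourier power at 24 h
reaches the observed power, times the fraction of background genes whose
absolute amplitude (max − min) reaches the observed amplitude. The
original method is published without closed formulas, so this
product-of-empirical-p form is documented here as the package's variant.
`n_perm = 1000` keeps the permutation component's resolution at 0.001,
which is fine-grained enough to rank a genome-scale matrix. The
whole-matrix scorer (`rhythm_scores()`) draws one permutation set per
call and shares it across genes — permutation draws are i.i.d. across
genes anyway and sharing makes genome-scale scoring linear in the gene
count — while the per-profile function draws its own; both are
deterministic given `seed`.

### Consensus aggregation and selection

Each algorithm ranks all genes (rank 1 = most rhythmic, average ranks on
ties; a missing score ranks last and is logged). Ranks are summed into a
cumulative rank and re-ranked to an ordinal *normalized rank*; cumulative
ties break by smaller JTK p then lexicographic gene ID so the ordering is
deterministic. Selection takes genes with normalized rank at most
`cutoff_n` **and** JTK p at most `p_gate = 0.06`. The rank cutoff is a
deliberate study choice rather than an automatic knee-point: score
distributions of periodicity algorithms are not bimodal, so
`cohort_chunks()` exposes successive 500-gene heat-map cohorts in
consensus order for the visual inspection by which the cutoff is fixed.
The normalized rank is computed before the JTK gate is applied, so a
gated-out gene keeps its consensus position in reports.

## Cross-species comparison

Ortholog groups (two-column `group_id`/`gene_id` text; species membership
resolved against explicit per-species gene universes, never parsed out of
IDs except in the synthetic fixtures) are typed by where rhythmicity
lives:

| Type | Definition |
|------|------------|
| 1 | at least one rhythmic gene in each species |
| 2 | rhythmic species-A gene(s); species-B members present, none rhythmic |
| 3 | mirror of Type 2 |
| 4 | rhythmic species-A gene(s), no species-B members |
| 5 | mirror of Type 4 |

Rhythmic genes outside any group are typed 4/5 by species; arrhythmic
singletons are ignored, and groups with no rhythmic gene stay untyped.
Type 1 groups refine to those with exactly **one** rhythmic gene per
species (arrhythmic paralogs do not count), which makes the cross-species
phase comparison one-to-one; Types 2/3 refine to pure splits in which
every rhythmic-side gene is rhythmic and every other-side gene is
arrhythmic.

The phase call is the hour of maximum abundance (earliest hour on ties).
For a refined pair the phase shift is the circular distance
`min(|a - b|, 24 - |a - b|)`, in [0, 12] h, and the pair is *synchronized*
when the shift is at most 4 h — the boundary is inclusive, matching the
"within 4 h" definition; no curated reference pair sits on the boundary,
so the choice is documented rather than empirically distinguishable.
Species-restricted rhythmic genes (Type 5) can be further categorised
with `taxon_presence_classify()` from a homolog hit table over a CAM /
non-CAM taxon panel: shared, CAM-only, non-CAM-only, or
species-specific.

Co-expression networks (`build_gcn()`) connect genes whose *signed*
Spearman correlation reaches 0.8 — the signed coefficient, not its
absolute value, so perfect anti-phase pairs are not edges. Correlations
are computed block-wise on rank-transformed profiles, so memory scales
with the block size squared, not the gene count squared. Constant
profiles have undefined correlations and stay as isolated, warned-about
nodes. Networks export losslessly to a TSV edge list plus node table or
to GraphML, and `autoplot()` draws the circular phase-coloured layout in
which a rhythmic set appears as a chronological ring.

Core-clock profiling (`profile_clock_genes()`) reports, per candidate,
mean FPKM, absolute amplitude (max − min), fold-change (max/min, missing
when the minimum is 0), normalized rank, and JTK p, then applies the
conjunctive filter amplitude > 10 FPKM, fold-change > 2, JTK p <= 0.05.
The inequalities are strict for amplitude and fold-change and inclusive
for p, and a missing value fails its criterion — so a candidate removed
by the max-FPKM expression filter (missing rank and p) or with an
undefined fold-change necessarily fails. The bundled curated tables
(`clock_ortholog_params()`, `tf_ortholog_pairs()`) carry the reference
clock-ortholog parameters and the 40 one-to-one rhythmic TF ortholog
pairs used by the acceptance checks.

## The synthetic generator

`simulate_diel_matrix()` emulates the data structure the pipeline
consumes: one 24-h cycle, a uniform grid (12 points at 2-h steps by
default), one replicate per time point, non-negative FPKM.

Rhythmic genes follow

```
baseline + A * max(0, cos(2*pi*(t - phase)/24))^k + noise
```

with `k = 1` ("cosine", a half-wave rectified cosine — expression cannot
go negative) or `k = 4` ("peaked", visibly sharper while smooth), each
used for half of the rhythmic genes by default. Phases are drawn
uniformly on the grid unless fixed; `true_amplitude = A` equals the
noiseless profile's absolute amplitude. Defaults — baselines uniform on
2–10 FPKM, amplitudes uniform on 5–50 FPKM — put rhythmic signal
comfortably above the max-FPKM floor while spanning weak to strong
cyclers, the range over which detection is informative at this scale.
Noise is i.i.d. Gaussian per time point, truncated at zero:
`noise_frac * A` for rhythmic genes and, CV-style, `noise_frac *
baseline` for arrhythmic genes, since measurement scatter in FPKM data
tracks expression level. All randomness flows from a single `seed`.

`simulate_ortholog_scenario()` adds the two-species structure: requested
counts of Type 1–5 groups are built directly from the truth labels (one
rhythmic gene per species for Type 1, rhythmic/arrhythmic pairs for
Types 2/3, single-species groups for Types 4/5), arrhythmic filler genes
pad each species, and any *extra* rhythmic genes implied by
`frac_rhythmic` join existing Type 1 groups, which leaves every type
count unchanged. Classifying the emitted groups with the truth labels
therefore reproduces the requested counts exactly, at any seed —
the round-trip the test suite exercises.

What the generator does **not** emulate: multi-day or free-running
(constant-condition) designs, so light-driven and clock-driven rhythms
cannot be distinguished — the data are entrained, single-cycle, like the
real matrices; read-level RNA-seq noise (counts, dispersion, library
effects); correlated noise across genes; asymmetric waveforms beyond the
rectified-cosine family. Passing tests on this generator show the
pipeline's logic is correct under its stated model, not that real tissue
data meet that model.

## Numerical choices and edge cases

- Cosine reference values are rounded to 9 decimals before tie-grouping
  so grid symmetry produces exact tie groups.
- JTK per-lag minima tie-break to the earliest lag hour; the exact-null
  tail includes the observed value (`P(C >= c_obs)`).
- `rank()` with average ties everywhere a rank is taken (profiles,
  scores, Spearman).
- pchip resampling extends the cycle periodically when the target grid
  leaves the sampled range (the 24-h sample is prepended at hour 0 before
  interpolating a 4..24-h series down to 2 h), justified by the 24-h
  periodicity of the diel design; values at source knots are reproduced
  exactly and monotone segments never overshoot.
- Constant profiles: JTK p 1 with missing lag, Lomb-Scargle power 0,
  periodicity-regulation score 1, z-score all zeros with a warning,
  network node without edges.
- Fold-change is reported missing when the profile minimum is 0; missing
  values always fail the clock filter.
- Empirical-fraction comparisons (`>=` on permuted power and background
  amplitude) use a 1e-12 slack so exact re-draws of the observed value
  count as ties, not wins.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
matrices of 300–1,000 genes x 12 time points with 200–1,000 permutations
for the empirical score, and on the 40-pair and 22-row curated reference
tables; the brute-force JTK oracle enumerates up to 8! orderings. These
sizes exercise every code path at desk scale. The genome-scale analyses
the pipeline is designed for (tens of thousands of genes, millions of
network edges) use the same code paths — the network builder is blocked
precisely so that scale stays memory-bounded — but their published
summary counts depend on the original two-species datasets and are not
reproduced here.

## Known limitations

- **The exact JTK gate is conservative on 12-point single-cycle data.**
  With cosine references, a k = 4 peaked profile carries ordering
  information in only about 5 of 12 samples; at 20% noise a substantial
  fraction of genuinely peaked cyclers exceed the 0.06 JTK gate, and even
  rectified cosines lose some sensitivity relative to full sinusoids.
  Consensus *ranking* degrades much less than the gate does — the
  regulation component rescues peaked genes in the cumulative rank — so
  the gate dominates end-to-end sensitivity under the generator's
  waveform mixture. Asymmetric reference waveforms would close this gap
  but are deliberately out of scope.
- Only the 24-h period is tested; damped, non-24-h, or multi-period
  rhythms are out of scope.
- The de Lichtenberg variant is this package's reconstruction of a
  method published without formulas; scores are comparable within a
  matrix, not across studies.
- The synchrony threshold (4 h) and the co-expression cutoff (0.8) are
  fixed conventions of the comparison, not fitted quantities.

## A worked micro-example

```{r example}
sc <- simulate_ortholog_scenario(
  c(T1 = 8, T2 = 4, T3 = 4, T4 = 2, T5 = 2),
  noise_frac = 0.1, seed = 1
)
cl <- classify_types(
  sc$groups,
  rhythmic_a = sc$truth_a$gene_id[sc$truth_a$is_rhythmic],
  rhythmic_b = sc$truth_b$gene_id[sc$truth_b$is_rhythmic],
  all_genes_a = sc$truth_a$gene_id,
  all_genes_b = sc$truth_b$gene_id
)
count(cl$group_types, type)

phases <- bind_rows(
  tibble::tibble(
    gene_id = sc$truth_a$gene_id,
    phase_call_h = apply(as.matrix(sc$expr_a[, -1]), 1, phase_call,
                         grid = diel_grid(sc$expr_a))
  ),
  tibble::tibble(
    gene_id = sc$truth_b$gene_id,
    phase_call_h = apply(as.matrix(sc$expr_b[, -1]), 1, phase_call,
                         grid = diel_grid(sc$expr_b))
  )
)
phase_pairs(cl, phases)
```
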