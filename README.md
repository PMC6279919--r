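# dielcompare

Comparative analysis of diel (24-hour light/dark) transcriptome
rhythmicity between two plant species.

## What it is for

CAM plants such as *Kalanchoë fedtschenkoi* fix CO2 at night and invert
their stomatal rhythms relative to C3 plants such as *Arabidopsis
thaliana*; how the circadian clock's transcriptional output was rewired
during that evolutionary transition is visible in which genes cycle over
one diel period and when they peak. `dielcompare` is for researchers
comparing single-cycle gene-expression time courses (one FPKM profile per
gene, e.g. 12 samples at 2-h intervals) across species linked by ortholog
groups. It provides:

- **Rhythmicity detection by consensus.** Three periodicity scores per
  gene — a rank-based JTK-CYCLE test with an *exact* concordance null
  (Gaussian-binomial / Harding convolution, Bonferroni over the distinct
  lag orderings), a fixed-period Lomb–Scargle periodogram with the
  single-frequency exponential null, and an empirical periodicity ×
  regulation score (Fourier power vs time-order permutations × amplitude
  vs background). Per-algorithm rankings are summed and re-ranked; the
  high-confidence set is `normalized_rank <= cutoff_N` **and**
  `JTK p <= 0.06`.
- **Ortholog rhythmicity typing.** Groups classify into five
  conservation types (rhythmic in both; rhythmic in one with arrhythmic
  or with no orthologs in the other), with refinements to one-to-one
  rhythmic pairs and pure rhythmic/arrhythmic splits.
- **Circular phase analysis.** Phase call = hour of maximum abundance;
  phase shift = `min(|a-b|, 24-|a-b|)` in [0, 12] h; a pair is
  *synchronized* when the shift is within 4 h.
- **Phase-annotated Spearman co-expression networks** at a signed
  `rho >= 0.8` cutoff, with TSV/GraphML export and circular
  phase-coloured plots.
- **Core-clock profiling**: amplitude (max−min), fold-change (max/min),
  and JTK p per candidate, filtered at amplitude > 10, fold-change > 2,
  p <= 0.05.
- **A two-species synthetic generator** with known truth (waveforms,
  phases, amplitudes, ortholog types) so the whole pipeline is testable
  offline.

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()` / `glance()` / `autoplot()` methods for the fitted objects.

## Worked example

Detection on a synthetic 400-gene matrix (40% rhythmic, 10% noise), then
the curated cross-species reference tables:

```r
library(dielcompare)

sim <- simulate_diel_matrix(n_genes = 400, frac_rhythmic = 0.4,
                            noise_frac = 0.1, seed = 7)
det <- detect_rhythmic(sim$expr, cutoff_n = 160, n_perm = 500, seed = 8)
det
#> <rhythm_detection> 400 genes, 115 rhythmic (normalized rank <= 160, JTK p <= 0.06)

tidy(det)[1:4, c("gene_id", "jtk_p", "dl_score", "normalized_rank", "phase_call_h")]
#> # A tibble: 4 × 5
#>   gene_id       jtk_p dl_score normalized_rank phase_call_h
#>   <chr>         <dbl>    <dbl>           <int>        <dbl>
#> 1 spA_g0095   8.90e-5        0               1            4
#> 2 spA_g0036   2.60e-4        0               2           18
#> 3 spA_g0157   2.60e-4        0               3            8
#> 4 spA_g0156   2.60e-4        0               4           10
```

160 genes make the rank cutoff but only 115 also pass the 0.06 JTK gate:
the exact, Bonferroni-corrected JTK test is conservative on 12-point
single-cycle data, especially for sharply peaked waveforms (see the
methods vignette's limitations section).

The bundled reference tables reproduce the published cross-species
summaries from their printed inputs:

```r
tab <- tf_ortholog_pairs()                      # 40 TF ortholog pairs
tab$shift_h <- phase_shift(tab$kfed_phase_h, tab$ath_phase_h)
tab[1:3, c("kfed_id", "kfed_phase_h", "ath_id", "ath_phase_h", "shift_h")]
#> # A tibble: 3 × 5
#>   kfed_id         kfed_phase_h ath_id    ath_phase_h shift_h
#> 1 Kaladp0057s0097            2 AT1G09530          20       6
#> 2 Kaladp0015s0032            4 AT4G38890          16      12
#> 3 Kaladp0003s0081            6 AT5G42200          12       6

clock <- clock_filter(clock_ortholog_params())  # 22 clock orthologs
sum(clock$passes)
#> [1] 10
```

All 40 recomputed shifts match the table's reported column, every pair is
unsynchronized (shift > 4 h), and exactly 10 of the 22 core-clock
orthologs pass the amplitude/fold-change/significance filter.

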