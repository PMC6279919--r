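Package: dielcompare
Title: Comparative Analysis of Diel Transcriptome Rhythmicity Between Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting rhythmic gene expression in single-cycle
    24-hour (diel) transcriptome time courses and for comparing rhythmicity
    across species through ortholog groups. Implements three periodicity
    detection algorithms (a rank-based JTK-CYCLE test with an exact
    concordance null, a fixed-period Lomb-Scargle periodogram, and an
    empirical periodicity-times-regulation score), consensus rank
    aggregation with a cumulative-rank cutoff and a JTK p-value gate,
    classification of ortholog groups into five rhythmicity-conservation
    types, circular phase-shift and synchrony analysis of ortholog pairs,
    Spearman co-expression networks annotated by phase, and circadian
    parameter profiling of core clock gene candidates. Includes a
    two-species synthetic data generator with known ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
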