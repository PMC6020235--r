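Package: diffacet
Title: Differential Histone-Acetylation and Expression Analysis from Consensus Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for two-group ChIP-seq and RNA-seq studies of
    histone acetylation (e.g. H3K27ac). Builds a consensus region set from
    per-sample peak calls (stretch to a minimum width, merge overlapping
    intervals, keep autosomal regions supported by at least two samples),
    quantifies occupancy per region and sample, tests regions and genes for
    differential signal with a negative-binomial Wald engine (median-of-ratios
    normalization, moments-plus-trend moderated dispersion, Benjamini-Hochberg
    correction), explores sample structure (quantile normalization,
    hierarchical clustering, PCA of top-variable regions, Manhattan tables),
    annotates regions to genes within a window of the transcription start
    site, quantifies acetylation-expression direction concordance, and scores
    transcription-factor binding-motif enrichment in foreground versus
    background sequences with log-odds PWM scanning and Fisher's exact test.
    A synthetic-data module generates complete input bundles with known ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    cluster,
    DESeq2,
    digest,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
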