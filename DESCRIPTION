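Package: atacreg
Title: Open-Chromatin Motif Scanning, Enrichment and Reporter-Assay Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for linking transcription-factor
    binding motifs to candidate regulatory elements and bench validation data.
    Builds consensus open-chromatin peaks from replicate ATAC-seq peak calls,
    annotates them against gene models, clusters position weight matrices into
    averaged consensus motifs, calibrates log-odds scan thresholds at a target
    empirical false-positive rate on background sequence, and tests motif
    over-representation with one-sided Fisher exact tests under Bonferroni
    correction. Companion statistics cover qPCR relative quantification by
    2^-ddCt with tissue normalization, organ-enriched gene selection,
    reciprocal-best-hit orthology, dual-luciferase normalization with a
    pooled-sum bootstrap synergy test, and ChIP-qPCR fold enrichment by the
    signal-over-background method. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable at desk
    scale.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
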