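Package: altipop
Title: Population-Transcriptomic Inference of Altitudinal Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting altitudinal adaptation from transcriptome-wide
    SNP and expression data in small multi-population designs. Implements
    per-population diversity statistics (nucleotide diversity, Watterson's
    theta, Tajima's D), pairwise differentiation (Hudson's FST, Nei's GST,
    Weir-Cockerham FST), locus-specific branch length (LSBL) selection scans,
    neighbor-joining and PCA population structure with a permutation test of
    group separation, a rejection Approximate Bayesian Computation model of
    per-transcript SNP density, RPKM-based differential expression with the
    ANOVA + FDR rule, and Hedges' g random-effects meta-analysis with
    meta-regression. A seeded synthetic-data generator produces
    three-population variant tables, transcript annotations and count matrices
    with the statistical structure the analyses assume, so the whole chain is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
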