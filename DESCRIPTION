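Package: methsubtypes
Title: Discovery and Cross-Cohort Replication of DNA Methylation Disease Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-driven discovery of DNA-methylation-defined disease subtypes
    from cortical array data and their replication across independent cohorts.
    Implements covariate residualization and variability filtering of beta
    matrices, dual (Ward-D2 hierarchical and k-means) clustering with elbow and
    normalized-mutual-information model selection, sparse partial least squares
    discriminant analysis with label-randomization robustness, median-profile
    correlation block matching and convex-hull latent-space replication with
    hypergeometric tests, subtype epigenome-wide association with surrogate
    variables, empirical-Bayes bias/inflation correction and inverse-variance
    meta-analysis, set-overlap and regulatory/cell-type enrichment with
    conditional maximum-likelihood odds ratios, Bayesian colocalization via
    Wakefield approximate Bayes factors, bulk transcriptomic differential
    expression with a cross-cohort consensus filter and CpG-gene window
    correlations, microglial-state abundance, control-anchored PCA activation
    scoring with permutation separation tests, pseudobulk differential
    expression, and morphology group statistics. A seeded multi-cohort
    synthetic-data generator with a truth registry makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    edgeR,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    metafor,
    limma,
    mclust,
    jsonlite
Config/testthat/edition: 3
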