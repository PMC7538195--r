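Package: heatsol
Title: Heat-Shock Proteome Solubility, Disaggregation Kinetics and Thermal Stability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for proteome-wide protein solubility under heat
    shock in human cells, quantified by dynamic SILAC and TMT reporter
    intensities. Provides a synthetic-data generator with planted ground truth;
    quality filtering, additive batch correction, variance-stabilizing glog
    calibration with light-to-heavy coefficient transfer, and left-censored
    imputation; aggregator calling by empirical-Bayes moderated t-statistics
    with a fold-change gate; linear disaggregation-rate estimation and feature
    correlations under a Shapiro-Wilk test gate; sequence-derived hydropathy,
    isoelectric point, molecular weight and Hsp70-binding-motif features;
    protein-complex coherence testing against a scrambled-complex permutation
    null; a two-dimensional thermal-proteome-profiling stability score with
    replicate-resampling bootstrap, per-round z-standardization and dual
    local/global FDR hit calling; and shared hypergeometric and Fisher
    enrichment utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
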