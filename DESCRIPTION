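Package: methex
Title: Coupled DNA Methylation and Gene Expression Analysis for Two-Group Tumor Contrasts
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Region-level aggregation of Illumina 450K-style beta values,
    empirical-Bayes moderated two-group differential testing of methylation
    (M-values) and log2 expression, Benjamini-Hochberg adjustment, quadrant
    classification of genes that are simultaneously differentially methylated
    and differentially expressed (DMEGs), leave-one-out cross-validated
    classifier evaluation with ROC/AUC and covariate stratification, and
    drug-target cross-referencing of upregulated DMEGs. Ships a synthetic
    two-group cohort generator with planted, region-clustered effects and a
    machine-readable truth table so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
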