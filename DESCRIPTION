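Package: anchorsig
Title: Anchor-Gene Differential Expression, Enrichment Scoring, and
    Survival Stratification for Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for relating the expression of anchor genes (for
    example the Notch ligands and receptors JAG1/2, DLL1/3/4, NOTCH1-4)
    to transcriptome-wide co-expression, pathway activity, and patient
    survival in bulk expression cohorts.  Per-anchor differentially
    expressed gene (DEG) sets are built by a Pearson correlation
    prefilter followed by a permutation-based significance analysis of
    microarrays (SAM) with per-gene false discovery rates.  Gene-set
    activity is scored per sample by single-sample gene set enrichment
    analysis (ssGSEA) and per contrast by two-class GSEA with
    normalized enrichment scores and permutation FDR.  Samples are
    dichotomized by a mean +/- standard-error rule, signatures are
    classified positive or negative by summed correlation with the
    anchors, and groups are compared by Kaplan-Meier estimation and
    k-group log-rank tests, including a combined four-group analysis.
    A synthetic-cohort generator with planted co-expression modules,
    latent signature activities, and log-linear exponential survival
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival
Config/testthat/edition: 3
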