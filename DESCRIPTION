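Package: sigact
Title: Absolute Single-Sample Gene Signature Activation Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls the activation state (low, independent, high) of gene
    expression signatures. Provides a cohort-level rank-sum permutation
    procedure (the region of independence, ROI) that partitions samples into
    three activation classes for any directed gene signature; a winnowing step
    that separates informative from uninformative signatures via a
    gene-label-permutation control; and an absolute single-sample classifier
    built from within-sample gene-pair rules combined by naive Bayes, trained
    against ROI gold-standard labels so that activation can be called from one
    expression profile with no comparison cohort. Includes agreement statistics
    (Cohen's kappa with large-sample significance, exact association tests,
    Benjamini-Hochberg FDR), a cohort-composition instability experiment
    contrasting relative z-score scoring with the absolute classifier, and a
    synthetic-cohort generator with planted low/independent/high structure for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
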