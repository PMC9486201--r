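Package: iegpi
Title: Immune-Escape Gene Prognosis Index Construction and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds and evaluates weighted prognostic gene-expression
    signatures of the immune-escape gene prognosis index (IEGPI) family:
    per-cohort median-dichotomized univariate Cox screening of a gene panel,
    inverse-variance (fixed- or random-effects) meta-analytic pooling of
    hazard ratios across cohorts, construction of a (HR-1)/SE weighted
    z-score composite per sample, survival-optimal cutpoint selection and
    high/low stratification, single-sample gene-set enrichment (ssGSEA)
    immune-infiltration scoring, tumor mutational burden summaries, and
    immunotherapy-response discrimination metrics. Includes a multi-cohort
    survival/expression simulator with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
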