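Package: txcohort
Title: Two-Group Transcriptomic Cohort Comparison Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for comparative transcriptomic
    analysis of a two-group patient cohort: Table-1 style contingency and
    rank-test cohort statistics, gene-set pathway activity scoring,
    covariate-adjusted per-feature logistic association with
    Benjamini-Hochberg false-discovery control, aggregation of prognostic
    signatures into an average genomic-risk score, correlation-weighted
    drug-response scoring, consensus clustering over an immune gene panel,
    and delta-Ct qPCR validation arithmetic. Ships a synthetic cohort
    generator with planted effects so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
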