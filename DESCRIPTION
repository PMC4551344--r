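Package: PDACsig
Title: Survival-Signature Discovery, Hypoxia Scoring and Collagen Texture
    Analysis for Pancreatic Cancer Cohorts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery of PCA-metagene survival signatures from bulk
    expression cohorts by FAST-statistic permutation screening and local
    false discovery rate selection, with leave-one-out cross-validated
    evaluation and a hazardous/protective transcript partition.
    Cross-cohort and cross-species risk scoring, hypoxia meta-signature
    construction from gene-set collections with a VEGFA sign anchor,
    hypergeometric over-representation with Benjamini-Yekutieli
    correction, the supporting survival and association statistics, and
    gray-level co-occurrence texture analysis of second harmonic
    generation collagen image stacks with a double-exponential
    decay-distance summary. Includes synthetic-data generators for
    survival cohorts, gene-set collections and fibrillar image stacks so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
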