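Package: rdikit
Title: Computational Ras Dependency Scoring from Single-Sample Gene Set
    Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Scores bulk expression profiles (microarray-like intensities or
    RNA-seq counts) against Ras-dependency gene signatures with a from-scratch
    single-sample GSEA (ssGSEA) engine, standardises the resulting scores into
    computational Ras dependency indices (RDIs), compares them with
    experimentally measured RDI tables, selects dependency extremes,
    derives differentially expressed genes between extremes, assembles
    Fisher-exact pathway-enrichment pattern (PPEP) matrices, tests pairwise
    signature overlap, and associates scores with censored survival via a
    univariate Cox model plus a cutpoint-scan (gradient scan) statistic.
    A synthetic-data generator with planted ground truth makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
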