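Package: CellSigScore
Title: Cell-Cluster Gene Signatures and Single-Sample Enrichment
    Classification of Bulk Tumors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives cell-cluster gene signatures from droplet scRNA-seq
    UMI counts (QC, library-size normalization, PCA, shared-nearest-neighbor
    graph clustering, one-vs-rest Wilcoxon markers) and scores bulk tumor
    expression profiles against those signatures with a from-scratch gene
    set variation analysis statistic (Gaussian kernel CDF, symmetrized
    ranks, weighted Kolmogorov-Smirnov random walk). Tumors are classified
    by their highest-scoring cluster, cross-tabulated against ER/PR/HER2
    receptor subtypes, and compared by Kaplan-Meier curves, log-rank and
    log-rank trend tests, and Mantel-Haenszel hazard ratios. A seeded
    negative-binomial simulator for single-cell counts and mixture bulk
    tumors with exponential survival provides ground-truth data for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    survival,
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
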