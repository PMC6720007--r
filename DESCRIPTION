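Package: miRTraffic
Title: Network-Based miRNA Candidate Prioritization and Circulating
    Biomarker Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a complete candidate-microRNA prioritization and
    biomarker-evaluation workflow for case/control cohort studies:
    detection filtering and differential expression of log2 microarray
    signal with FDR control, consensus integration of predicted
    miRNA-target interactions across prediction databases, construction
    of a heterogeneous miRNA-gene / protein-protein interaction network
    with modularity-based module decomposition and exact betweenness
    ("traffic") scores, hypergeometric over-representation analysis with
    a non-redundancy filter, and two-group biomarker statistics with ROC
    / Youden evaluation and rank correlation against continuous
    covariates. A synthetic-data module generates every pipeline input
    with known ground truth so the full workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'biomarker.R'
    'enrichment.R'
    'expression.R'
    'io.R'
    'miRTraffic-package.R'
    'network.R'
    'pipeline.R'
    'synthdata.R'
    'targets.R'
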