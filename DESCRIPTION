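Package: coexpStrata
Title: Sex- and Age-Stratified Gene Co-Expression Network Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers and compares mutual-information gene co-expression
    networks across sex and age strata of bulk RNA-seq cohorts. Provides a
    negative-binomial simulator with planted co-expression modules emulating
    a six-stratum (sex x age group) muscle cohort design, count filtering and
    quantile normalization, a plug-in mutual-information estimator with
    data-processing-inequality pruning and top-k edge retention, edge- and
    gene-set overlap statistics (Jaccard), conserved and unique interaction
    extraction, a bootstrap null model for the size of the largest connected
    component of unique subnetworks, and local hypergeometric gene-set
    over-representation with Benjamini-Hochberg correction. A single
    orchestrator runs the full pipeline deterministically and records a
    checksummed manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    limma,
    jsonlite,
    yaml,
    withr,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: NetworkInference, GeneExpression, Network, Transcriptomics
RoxygenNote: 7.3.3
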