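Package: stepfeats
Title: Correlation-Based Feature Selection for Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects a minimally redundant, marker-enriched feature (gene) set
    for clustering single-cell RNA-seq and scATAC-seq count matrices. Candidate
    genes are scored by a binned z-score of their correlation range in the
    gene-gene Pearson correlation matrix, reduced to a non-redundant seed set
    by stepwise regression on that matrix, expanded by guilt-by-association
    over the correlation network, and sized by maximizing the Density Index,
    a label-free proxy for cluster separation in principal-component space.
    Includes a negative-binomial synthetic-data generator with planted cell
    types, and silhouette / AUROC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster,
    pROC,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
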