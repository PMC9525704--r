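Package: panelomics
Title: Graph-Based Feature Panels and Association Rules for Omics Subtype Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers compact, non-redundant panels of transcriptomic features
    (mRNAs, miRNAs) that discriminate cancer subtypes, and mines the association
    rules that link those features to each subtype. Features are first screened
    with the arithmetic-to-geometric-mean (AMGM) dispersion ratio, then embedded
    in a weighted feature graph blending AMGM relevancy with cosine redundancy,
    partitioned into communities by Louvain modularity maximisation, and reduced
    to candidate panels by per-community maximum-independent-set selection.
    Panels are evaluated with a self-organising stacked auto-encoder classifier
    (accuracy, per-class F1 and ROC AUC), and FP-Growth association-rule mining
    with repeat-count ranking identifies the molecules that dominate each
    subtype's rules. A synthetic-cohort generator with planted subtype signal,
    redundant feature blocks and planted co-occurrence rules makes every stage
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    nnet,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
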