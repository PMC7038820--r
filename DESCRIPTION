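Package: mixdag
Title: Structure Learning of Directed Acyclic Graphs from Mixed Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Recovers a sparse directed acyclic graph over mixed continuous
    and categorical variables from cross-sectional observational data. The
    three-stage hybrid algorithm first identifies each node's Markov blanket
    by nodewise L1-penalized generalized linear regression with EBIC tuning,
    then prunes the resulting mixed graphical model to the DAG skeleton with
    a permutation test of conditional independence on residual partial
    correlations inside a PC-stable loop, and finally orients the skeleton
    by greedy BIC hill climbing with optional direction constraints (for
    example, forcing SNP nodes to be sources). Includes a structural
    equation simulator for random mixed-type DAGs and sensitivity,
    specificity and false discovery rate metrics for edge recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    nnet,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
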