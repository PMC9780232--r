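Package: scDEbench
Title: Benchmarking Differential Expression Strategies for Single-Cell
    RNA-Seq with Hierarchical Count Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates droplet single-cell RNA-seq counts for two-group
    (case/control) designs with cells nested in individuals, donor-level
    random effects, negative-binomial noise and logistic dropout, with
    known differentially expressed genes injected at configurable fold
    changes. Runs a roster of differential-expression strategies --
    pseudobulk aggregation (mean or sum per individual), pseudoreplication
    tests that treat cells as independent replicates (Welch t, Tobit,
    two-part hurdle), and cluster-aware generalized estimating equations --
    on identical simulated datasets under a strict seeding contract, and
    scores them with balanced measures: Matthews correlation coefficient,
    empirical type-1 error, and sensitivity at a fixed false-positive rate
    read from ROC curves. Includes an orchestrator for factorial benchmark
    grids over numbers of individuals and cells per individual, including
    imbalanced designs and ROC studies across proportions of
    differentially expressed genes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    survival,
    yaml,
    dplyr,
    tibble,
    ggplot2,
    rlang,
    stats,
    utils,
    methods,
    tools,
    parallel
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
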