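Package: ggmbench
Title: Benchmarking Large-Scale Network Recovery from Correlated Gaussian
    Time Series
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A simulation-and-evaluation framework for studying how well
    pairwise correlations and three partial-correlation estimators
    (shrinkage, Moore-Penrose pseudoinverse, graphical lasso) recover
    known network structure from short, autocorrelated multivariate
    Gaussian time series. Provides seeded generators for random,
    small-world (acquaintance model) and preferential-attachment
    topologies, construction of valid Gaussian graphical models on a
    given topology, AR(1) multivariate time-series simulation,
    fixed-density edge selection, standard network metrics (path length,
    transitivity, small-worldness, betweenness, components), and
    true/false-positive-rate recovery evaluation overall and by degree
    bin, plus a hierarchical ROI fixture generator and consistency
    analyses for parcellated time-series matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
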