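Package: netgrow
Title: Stochastic Growth of Modular Networks and Their Topological Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows undirected networks by stochastic node, edge, and
    duplication/fusion events, optionally steered by an assortativity
    matrix over functional modules ("colors"). Provides topological and
    functional modularity measures (Newman's Q and assortativity r, the
    trace-form functional modularity Q_H), mixing-matrix estimation,
    small-world-ness statistics against Erdos-Renyi baselines,
    percolation (giant component) sweeps, and a Monte-Carlo search that
    reverse-engineers growth parameters from an observed degree
    distribution via threshold-binned RMS fitting and rank-sum
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
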