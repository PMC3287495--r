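Package: dbngrn
Title: Gene Regulatory Network Reconstruction with Dynamic Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs gene regulatory networks from time-series gene
    expression data with a two-slice dynamic Bayesian network (an initial
    network plus a stationary transition network). Structure is learned by a
    modified K2 greedy search that maximizes a decomposable Bayesian
    information criterion split over the two network components, with the
    REVEAL mutual-information lattice search and a timing-based candidate
    regulator prior as baselines. Includes a stochastic gene-network
    simulator with replicated time courses so that learning and
    precision/recall evaluation are fully testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    igraph,
    ggplot2,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
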