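Package: spreadrank
Title: Path-Reachability Spread Centrality and Influential Spreader Selection on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies influential spreaders in undirected contact networks.
    Computes a path-reachability spread centrality for local vital nodes
    (nodes above the mean degree) from the diversity, number and length of
    bounded simple paths between them, and selects a compact influential node
    set by iterative picking with neighbourhood attenuation followed by a
    giant-component dismantling criterion. Includes a discrete-time SIR
    Monte-Carlo engine for spreading and targeted-immunization experiments,
    five baseline centralities (degree, betweenness, k-shell, eigenvector,
    VoteRank), a scale-free network generator and an experiment driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
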