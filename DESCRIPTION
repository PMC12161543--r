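Package: controbs
Title: Driver, Sensor and Dual-Identity Nodes in Directed Networks
Version: 0.1.0
Authors@R:
    person("controbs", "developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Classifies every node of a directed network by its role in
    structural controllability and observability: driver nodes (receive an
    independent external input), sensor nodes (feed an independent output),
    dual-identity (DS) nodes (both), and ordinary nodes (neither). Roles are
    read off a single maximum matching of the bipartite representation of
    the adjacency structure, computed with the Hopcroft-Karp algorithm.
    Includes seeded generators for directed Erdos-Renyi and static-model
    scale-free networks, degree-preserving rewiring (the "rand-degree" null
    model), greedy leaf removal (core percolation), and an analytic theory
    that predicts the category fractions from the in-/out-degree
    distributions alone, with closed forms for the Poisson and static-model
    power-law cases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
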