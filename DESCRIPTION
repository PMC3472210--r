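Package: ionrank
Title: Essential Protein Ranking from Orthology and Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks proteins by predicted essentiality on an undirected
    protein-protein interaction network by combining an orthology-derived
    conservation score with neighbour propagation weighted by edge clustering
    coefficients, solved as a damped fixed point by Jacobi iteration.
    Includes the seven classical centrality baselines (degree, betweenness,
    closeness, subgraph, eigenvector, information, and edge-clustering-
    coefficient centrality), evaluation instruments (top-K accuracy,
    precision-recall curves, jackknife curves with random-assortment
    controls, connectivity and overlap breakdowns), parameter sweeps, and a
    seeded synthetic benchmark generator with planted complexes and
    conservation-shifted ortholog counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
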