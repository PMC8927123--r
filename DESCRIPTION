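Package: dyncomm
Title: Dynamical Communities and Nearly Equitable Partitions in Weighted
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects exact and nearly equitable partitions ("dynamical
    communities") in weighted directed networks.  Provides the iterative
    balanced-coloring refinement for exact equitable partitions, a
    k-medoids relaxation that sweeps over every candidate number of
    clusters, a correction cost measuring the minimum-norm modification
    of the adjacency matrix that makes a candidate partition exactly
    equitable, a swap-randomization significance test for the smallest
    statistically supported number of clusters, dynamics-based
    validation through consensus dynamics and coupled Rossler
    oscillators, and a comparison against modularity-based community
    structure via a pair-counting Jaccard index.  Includes a synthetic
    generator of networks with planted equitable partitions and two
    noise models, plus readers and writers for dense matrix, edge-list
    and Matrix Market formats.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    MASS,
    igraph,
    deSolve,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
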