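Package: ecmgraph
Title: Hierarchical Graph Analysis of Effective Connectivity Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph-theoretic characterization of group-level effective
    connectivity matrices (ECMs) estimated for large-scale resting-state brain
    networks. Transforms signed weighted directed ECMs into directed (WDCM) and
    undirected (WUCM) connectivity graphs, computes brain-level metrics
    (connection strength, self-inhibition summaries, small-world propensity
    with lattice and random weight-reassignment null models, weighted
    assortativity, and a reciprocal-edge balance statistic), aggregates them
    into 7x7 resting-state-network block matrices, screens group-difference
    matrices for regions with outlying average connectivity changes, and ships
    a synthetic connectome generator (block-structured ECM cohorts with planted
    differences, Watts-Strogatz weighted test graphs, and a linear
    neuronal-state forward simulator) so the whole pipeline is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
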