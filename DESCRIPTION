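Package: allokit
Title: Allosteric Communication Networks from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracing allosteric communication in proteins from
    molecular dynamics trajectories. Provides structural and dynamic
    observables (RMSD, RMSF, radius of gyration, native contacts, geometric
    hydrogen bonds, Shrake-Rupley solvent accessible surface area, essential
    dynamics and Boltzmann-weighted free-energy landscapes), a neural
    relational inference (NRI) engine that learns a probabilistic residue
    interaction graph from trajectory segments with a variational
    graph-neural-network encoder, Gumbel-softmax latent edge types and an
    MLP dynamics decoder, and network analysis of the inferred graphs
    (betweenness centrality, cross-region interaction strengths, Dijkstra
    shortest communication paths, relay-residue detection and druggable
    pocket prioritization). A synthetic spring-network Langevin simulator
    with planted interaction graphs supplies ground-truth test systems,
    including apo/bound scenario pairs with core rigidification, peripheral
    softening and added relay edges.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    yaml,
    rlang,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
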