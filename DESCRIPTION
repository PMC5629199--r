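Package: ecsampler
Title: Evolutionary-Couplings-Guided Adaptive Sampling of Molecular Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for adaptive sampling of molecular conformational
    dynamics guided by evolutionary couplings. Scores conformations by the
    change in the sum of coupled residue-pair distances (delta-SEC), builds
    Markov state models (transition counting, reversible maximum-likelihood
    estimation, implied timescales, tICA), generates state-to-state
    trajectories by kinetic Monte Carlo, extracts transition pathways by
    transition path theory, integrates a two-dimensional Brownian particle on
    rugged model potentials, and runs first-passage-time experiments that
    compare serial, random-adaptive and guided-adaptive sampling protocols
    on synthetic benchmark systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
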