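Package: hingeflex
Title: Hybrid EPR and Cross-Linking Analysis of Hinge Flexibility in a
    V-Shaped Two-Domain Dimer
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for hybrid solution-structure analysis of flexible
    multidomain proteins such as the DnaJ/Hsp40 cochaperone dimer.
    Provides crystal-structure geometry analyses (rigid-body
    superposition, non-crystallographic-symmetry RMSD, interdomain
    rotation angles, side-chain hydrogen-bond enumeration, sequence
    mass), a geometric tether-cone spin-label model for predicting
    label-label distance distributions, four-pulse DEER/ELDOR trace
    simulation and inversion by non-negative Tikhonov regularization,
    a coarse-grained Metropolis Monte Carlo sampler whose pseudo-energy
    combines a C-alpha clash penalty with an inverse-Boltzmann EPR
    distance-distribution term, a progressive-flexibility cross-link
    feasibility scan, and a synthetic-data generator producing V-shaped
    two-domain bead dimers with ground-truth ensembles and noisy DEER
    datasets.
License: MIT
Encoding: UTF-8
Imports:
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
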