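Package: sensillanet
Title: Simulation of Electrically Coupled Dendritic Processes in an Insect Sensillum
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-cable compartmental model of olfactory receptor neuron
    dendritic processes coupled by gap junctions inside a single basiconic
    sensillum. Each cable is a chain of passive compartments terminated by a
    Morris-Lecar active compartment; ohmic gap junctions connect passive
    compartments of different cables. The package provides a fixed-step
    network integrator, spike extraction and spiking-cable counting, preset
    ladder scenarios with calibrated stimulus amplitudes that exhibit the
    stronger-input-spread and weaker-input-cut filtering regimes, and a
    seeded stochastic generator of dendritic-bundle connectivity graphs
    calibrated to measured bead and adhesion-region statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
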