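Package: dgca3net
Title: Conductance-Based Simulation of a Dentate Gyrus-CA3 Micro-Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic simulation and analysis of a small hippocampal
    dentate gyrus-CA3 network built from Hodgkin-Huxley-type single
    compartment cells and a two-compartment Pinsky-Rinzel mossy cell,
    coupled by kinetic AMPA, NMDA and GABA_A synapses with a configurable
    CA3-to-DG backprojection.  Includes fixed-step Runge-Kutta integration,
    spike detection, interspike-interval bifurcation scans, Welch spectra
    and spectrograms with dominant-frequency extraction, zero-lag linear
    correlation analysis, and discharge-regime classification for studying
    interictal-to-seizure transition dynamics under increasing NMDA
    receptor conductance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
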