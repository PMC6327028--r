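Package: tasolv
Title: Transient Absorption Analysis of Electron Solvation and Attachment
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of picosecond pulse-radiolysis transient
    absorption experiments on excess electrons in viscous solvents.  Provides a
    synthetic time-wavelength absorbance generator with a known multi-species
    kinetic scheme (pre-solvated electron relaxation, quasi-free-electron
    scavenging by a solute, excited and ground solute anion radicals), global
    multi-exponential lifetime analysis with decay-associated spectra and
    instrument-response convolution, spectral peak tracking, MCR-ALS
    (multivariate curve resolution by alternating least squares) species
    deconvolution with SIMPLISMA-style initialization, neat-solvent reference
    subtraction, and exponential electron-scavenging (C37) yield modelling.
    Every analysis stage is verifiable by parameter recovery against the
    generator's ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
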