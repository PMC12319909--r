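Package: csfinflow
Title: Forward and Inverse Modeling of fMRI Inflow Signals for CSF Flow
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates time-of-flight inflow signals in multislice
    gradient-echo fMRI from arbitrary time-varying, bidirectional fluid
    velocities, using a Lagrangian spin-ensemble model with
    subject-specific flow-compartment anatomy. Provides the
    flow-enhanced spoiled gradient-echo signal equation for arbitrary
    excitation histories, slice excitation scheduling for simultaneous
    multislice protocols, a stochastic generator of physiologically
    structured training velocities and anatomies, a physics-trained 1D
    convolutional network that inverts measured three-slice inflow
    signals to velocity time series, and preprocessing utilities for
    fMRI and phase-contrast region-of-interest data (partial-volume
    scaling, baseline and filtering, cycle-locked averaging, Welch
    spectra, slice decay rates).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), RNifti, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
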