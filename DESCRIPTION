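Package: opsinkit
Title: Kinetic Modelling and Characterization of Light-Gated Ion Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and characterizing light-gated ion channels
    (opsins such as Channelrhodopsin-2) with three-, four-, and six-state
    Markov photocycle models. Provides light-stimulus waveforms and
    preconfigured voltage-clamp characterization protocols, a piecewise ODE
    simulation engine with an analytic propagator for rectangular pulses,
    automatic photocurrent feature extraction (peak, plateau, phase
    segmentation), a staged nonlinear least-squares fitting pipeline that
    recovers model parameters from photocurrent data sets, a synthetic-data
    generator for verification by parameter recovery, and exporters for
    NMODL mechanism files and network-simulator equation text.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: deSolve, minpack.lm, jsonlite, yaml, stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
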