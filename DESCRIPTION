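Package: stp300
Title: Stockwell-Transform Detection of P300 Evoked Potentials from
    Occipital EEG
Version: 0.1.0
Authors@R:
    person("stp300", "developers", email = "stp300@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for visual-oddball P300
    evoked potentials recorded from two occipital channels (O1, O2) at
    128 Hz. Provides a synthetic EEG generator reproducing the 3x4
    image oddball paradigm and published P1/P2/P3 component statistics,
    ERP preprocessing (mean subtraction, zero-phase 1-8 Hz filtering,
    epoch extraction, component peak statistics), a discrete 1-D
    Stockwell transform with a direct-summation reference oracle,
    band-averaged sliding-window statistical features, LDA and
    soft-margin SVM (linear, quadratic, RBF) classifiers, and a
    reproducible end-to-end pipeline with CSV and EDF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
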