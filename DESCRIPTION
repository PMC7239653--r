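Package: odplast
Title: Measurement Pipelines for Ocular Dominance Plasticity Experiments
Version: 0.1.0
Authors@R:
    person("Plasticity", "Lab", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipelines for the three measurement modalities used in
    studies of neuromodulator-gated ocular dominance plasticity in mouse
    primary visual cortex: Fourier extraction of periodic-stimulus intrinsic
    optical signals with ocular dominance index (ODI) mapping, detection and
    spontaneous-rate correction of strontium-desynchronized quantal EPSCs, and
    EPSP initial-slope quantification of spike-timing-dependent plasticity.
    Includes seeded synthetic-data generators with known ground truth for
    every modality, before/after session comparison, and a command-line entry
    point for end-to-end simulated or real-data runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
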