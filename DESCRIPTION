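Package: clcoupling
Title: Cross-Level Coupling Between Single-Neuron Spiking and Cortical Beta Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Characterizes cross-level coupling (CLC) between single-neuron spike
    trains and meso- and macro-scale oscillatory field activity in motor cortex.
    Provides Gabor analytic-signal filtering with amplitude normalization,
    equal-count binned rate mappings with sigmoid, cosine, von Mises and joint
    amplitude-phase fits, circular-shift permutation tests, split-half and
    cross-task stability analyses, inter-hemispheric phase-difference analyses
    including the distance law of pairwise phase concentration on a
    microelectrode array, ensemble rank-order state enumeration from fitted
    mappings, complex augmented-Gaussian multichannel models for spike-rate
    prediction, and a calibrated synthetic-data generator that emulates the
    statistical structure the analyses assume, so the full pipeline is testable
    without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
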