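Package: slowstates
Title: Up/Down-State Segmentation and Thalamo-Cortical Spike-Timing Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for cortical slow-oscillation recordings:
    segmentation of local field potentials (LFP) into up, down and
    indeterminate states by combining delta-band phase evidence with
    beta/low-gamma power evidence thresholded through a three-Gaussian
    mixture; juxtasomal and multi-unit spike detection; circular
    phase-locking statistics (Rayleigh test, locking strength, von Mises
    fits) with cumulative-distribution phase rescaling; spike-triggered
    instantaneous-firing-rate analysis against a constrained surrogate-spike
    null; and derivative-threshold latency estimation for optogenetically
    evoked down-to-up transitions. Includes a seedable synthetic-recording
    generator emulating thalamo-cortical slow-oscillation structure so the
    whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
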