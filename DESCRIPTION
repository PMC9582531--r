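Package: gaitGPM
Title: Gait-Phase Related EEG Power Modulations from Mobile Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of gait-phase related EEG power modulations
    (GPMs) recorded during overground walking under a 2x2 terrain-by-task
    design. Provides accelerometer-based gait-event detection with
    plausibility filtering and stride metrics, an EEG cleaning chain
    (resampling, zero-phase FIR band-pass, bad-channel detection, spherical
    spline interpolation, full-rank common average reference, line-noise
    removal, epoch rejection, ICA-based eye-artifact attenuation),
    Morlet time-frequency decomposition with gait-cycle time warping to 100
    phase bins and decibel baselining against quiet standing, spectral
    principal component analysis for muscle-artifact attenuation, a
    five-feature data-quality footprint, cluster-based within-subject
    permutation statistics, and a synthetic-data generator with ground truth
    so the whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
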