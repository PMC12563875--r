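Package: p300sttc
Title: Spatiotemporal P300 Analysis and Prior-Guided Transformer-CNN
    Classification for Two-Group Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying group differences in the P300 event-related
    potential and for classifying subjects from single-trial oddball EEG.
    Provides a synthetic two-group oddball-EEG generator (pink-noise
    background, fronto-central P300 topography, configurable amplitude
    attenuation and latency delay), a standard epoching pipeline (zero-phase
    band-pass, average reference, baseline correction, downsampling), a
    common spatiotemporal pattern (CSTP) filter learner with normalized
    log-variance features, channel-wise statistical comparisons with
    Bonferroni correction and effect sizes, a Transformer-CNN classifier
    with learnable channel prior weighting and a prior-masked attention
    window implemented with exact analytic gradients, and a subject-level
    cross-validation harness with an RBF-SVM baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    graphics,
    jsonlite,
    pROC,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
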