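Package: aisqa
Title: Signal Quality Assessment for Hand-Held Single-Lead ECG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the signal quality of single-lead ECG
    recordings acquired with dry metal-electrode hand-held devices, as used
    in large-scale atrial fibrillation screening. Includes an equivalent
    circuit model of the skin-electrode interface and the capacitively
    coupled amplifier input stage (a first-order high-pass that distorts
    beat morphology), a synthetic single-lead ECG generator with graded
    corruption and ordinal quality labels, windowed FFT/eCDF correlation
    motion-artifact detection, Pan-Tompkins R-peak detection, heart-cycle
    morphology averaging with dynamic time warping prototype clustering,
    a 22-feature multi-domain signal description, and Gaussian process
    regression of the features onto a continuous 0-3 quality index, with an
    evaluation suite (regression metrics, ROC, balanced accuracy,
    repeat-threshold curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    cluster,
    graphics,
    jsonlite,
    pROC,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
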