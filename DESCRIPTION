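Package: mmrtf
Title: Probabilistic Time-Frequency Mismatch Responses from Oddball EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the probabilistic time-frequency mismatch response
    (MMR-TF) from auditory oddball EEG recordings: zero-phase FIR filtering,
    re-referencing, epoching and joint-probability artifact rejection;
    trial-dimension PCA whitening and a 6-cycle complex Morlet continuous
    wavelet transform over 128 log-spaced scales; bootstrap difference
    surfaces mapped through a kernel-density CDF into per-point
    probabilities; a modified joint DISTATIS group analysis over spectral
    and temporal cross-product matrices; and quasi-likelihood feature
    extraction with band centroids and a surprise statistic. Includes a
    parameterized synthetic sleep-EEG oddball simulator with a known
    deviant-response cascade for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
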