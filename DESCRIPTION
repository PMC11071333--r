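Package: actidecode
Title: Activity-State Decoding from Six-Axis Wristband Inertial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Window-level human activity recognition for wrist-worn six-axis
    inertial recordings covering four physical-education movements
    (stationary, walking, running, squat). The pipeline mean-filters the raw
    accelerometer and gyroscope channels, cuts them into sliding windows,
    computes a 60-dimensional battery of per-channel statistical features,
    classifies each window with a from-scratch backpropagation neural network
    trained under mean-squared error, and smooths the predicted label sequence
    with a discrete hidden Markov model (scaled forward-backward, Viterbi
    decoding, Baum-Welch estimation, and supervised estimation from labeled
    sequences). A synthetic recording generator emulating the statistical
    structure of the four activities makes the whole method trainable and
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
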