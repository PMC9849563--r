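Package: gaitphase
Title: Continuous Gait-Phase Estimation from Vertical Load and Joint Angles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A device-agnostic pipeline for estimating the continuous gait
    phase (0-100% of the stride cycle) of walking and stair ascent from four
    wearable-sensor channels: weight-normalized vertical load and thigh, knee
    and ankle angles. Discrete stance/swing labels are extracted from the
    vertical load with a streaming z-score-style segmenter, converted into a
    continuous polar-coordinate phase target, and a small 1-D convolutional
    LSTM network (6,258 trainable parameters, implemented in compiled code)
    is trained to predict the phase from a 250 ms sensor history. Includes a
    synthetic gait-session generator with known ground truth, evaluation
    metrics (polar-space R-squared, circular phase error, median stride
    trajectories and their Pearson correlations), and a command-line
    interface over the full simulate/segment/label/train/predict/evaluate
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
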