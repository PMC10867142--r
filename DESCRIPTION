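Package: bovinecall
Title: Acoustic Feature Extraction and Classification of Cattle Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of dairy-cattle vocalizations:
    reading and writing of segmented call recordings (RIFF/WAVE PCM), Praat-style
    spectrograms and amplitude envelopes, extraction of 23 standard vocal
    parameters (fundamental-frequency statistics, spectral energy quartiles,
    amplitude-modulation metrics, harmonic-to-noise ratio, eight formant means,
    formant dispersal and Wiener entropy), a source-filter synthesizer producing
    labelled cattle-like calls with known ground truth, an explainable stacked
    bagging classifier (three searched base families, gradient-boosted
    meta-learner, majority vote over bootstrap instances) with leave-one-feature-out
    importance, and a compact convolutional-recurrent (CNN+GRU) spectrogram
    classifier. Includes a stratified k-fold evaluation harness for call-type
    (low- versus high-frequency) classification and individual-cow identification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    signal,
    ranger,
    glmnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
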