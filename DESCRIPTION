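Package: seizr
Title: EEG Seizure Detection with Wavelet Features and a 1D CNN-LSTM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end epileptic seizure detection from single- and
    multi-channel EEG. Reads Bonn-style plain-text segments and standard
    16-bit EDF recordings, windows and z-scores the signal, builds the
    per-channel discrete-wavelet (Daubechies) feature vector, and trains a
    1D convolutional-recurrent (CNN-LSTM) classifier with class-weighted
    stratified k-fold cross-validation. Includes an analytic layer-shape
    and parameter-count oracle for the network, a full confusion-matrix
    metric suite (sensitivity, specificity, accuracy, PPV, NPV, MCC, F1),
    ROC-AUC, fold-wise statistical model comparison, classical
    machine-learning baselines, architecture ablations, and a synthetic
    EEG generator so the whole pipeline is testable without any dataset
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    yaml,
    e1071,
    class,
    rpart,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
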