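Package: seegstate
Title: Spontaneous State Detection from Stereo-EEG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects spontaneous active versus idle brain states from
    continuous multichannel intracranial (stereo-EEG) recordings under an
    intermittent auditory-stimulus paradigm.  Provides a ground-truthed
    synthetic session generator, band-power and event-related-potential
    trace construction (comb notch, Laplacian re-referencing, Butterworth
    band-pass, Hilbert envelope), permutation-test channel selection,
    sliding-window time-domain feature extraction (amplitude, RMS, slope,
    line-length) with permutation feature selection and PCA, GMM-HMM state
    decoding with LDA/SVM/random-forest baselines under consecutive
    three-fold cross-validation, period-level detection metrics with onset
    and end timing analysis and permutation chance levels, and a
    three-class (own name / other name / idle) extension.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    mclust,
    MASS,
    e1071,
    randomForest,
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
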