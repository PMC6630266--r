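Package: semgfall
Title: Fall Detection from Surface Electromyography with a Dual-Branch
    Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for recognising falls among daily
    activities (walking, squatting, sitting) from four-channel surface
    electromyography sampled at 1500 Hz. Provides a synthetic sEMG
    generator with ground-truth burst annotations, cascaded Butterworth
    band-pass preprocessing (10-500 Hz), active-segment extraction by
    sliding-window mean short-term energy with calibrated static
    thresholds, Hamming-window spectrogram features reduced by principal
    component analysis, the classic myoelectric time-domain features
    (MAV, VAR, WL, RMS, ZC, SSC), an improved dual-parallel-channel
    convolutional network with ablation variants and classical baselines
    (RBF-SVM, LDA, KNN), and leave-one-subject-out evaluation reporting
    accuracy, sensitivity and specificity with falls as the positive
    class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    MASS,
    e1071,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
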