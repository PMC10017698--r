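Package: sleepscoreR
Title: Automated Sleep-Stage Scoring for Mouse EEG/EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Epoch-based automated scoring of vigilance states (Wake, NREM,
    REM) in mouse electroencephalogram (EEG) and electromyogram (EMG)
    recordings. Reads EDF/EDF+ polysomnography files, applies recording-level
    quality control, extracts a canonical 291-feature (or 153-feature,
    single-EEG) per-epoch spectral and temporal feature set after 1-40 Hz
    bandpass filtering, and scores 10-s epochs with a gradient-boosted
    decision-tree classifier (with multinomial logistic regression and random
    forest baselines). Provides inter-rater evaluation metrics (per-stage
    recall, precision, f1, agreement rate, Cohen's kappa), per-epoch additive
    (SHAP) feature attributions, a semi-Markov hypnogram and band-limited
    noise simulator for fully self-contained benchmarking, and a batch
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    signal,
    glmnet,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
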