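Package: upstate
Title: Closed-Loop Slow-Wave Stimulation Analysis: Up-State Detection,
    Imaginary-Coherency Networks, and Metamemory Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for closed-loop slow-oscillation
    stimulation experiments in sleep EEG. Provides a synthetic cohort generator
    (slow-wave oscillations with up-state-nested spindles over 1/f noise, lagged
    inter-channel coupling, stimulation-induced connectivity effects, and
    confidence-rating behavior with controllable metacognitive sensitivity), an
    emulated real-time detector of slow-wave up-states with phase-locking
    validation, Welch cross-spectral estimation of the imaginary part of
    coherency in canonical frequency bands, graph-theoretic network features,
    type-2 ROC metamemory sensitivity, and a cross-validated feature-selection
    and prediction stage (collinearity pruning, univariate filters, shadow-
    feature random-forest selection, logistic/ridge/linear models, repeated
    random-split folds, and bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
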