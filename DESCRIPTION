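Package: spocridge
Title: Person-Specific Decoding of Mental Rotation Reaction Times from EEG Band Power
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a person-specific machine-learning pipeline that predicts
    single-trial reaction times in a mental rotation task from multichannel EEG:
    ICA-based artifact removal, a ten-band zero-phase FIR filter bank, SPoC
    (Source Power Comodulation) spatial filtering via a generalized
    eigendecomposition of label-weighted covariances, log-variance band-power
    features, and closed-form ridge regression tuned by chronological
    sliding-window cross-validation. Includes exact linear SHAP attribution,
    intra- and inter-individual evaluation designs with a bootstrap paired test,
    and a synthetic-data generator that emulates the task schedule, behaviour and
    EEG source structure with known planted comodulation for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
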