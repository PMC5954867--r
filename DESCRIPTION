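Package: eegfatigue
Title: Real-Time EEG Fatigue Monitoring by Theta/Alpha Rhythm Deviation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting operator mental fatigue from single- or
    few-channel electroencephalography (EEG). Implements an end-to-end
    monitoring pipeline: amplitude-rule artifact flagging (50 microvolt
    criterion) and blind-source-separation artifact removal, wavelet-packet
    extraction of the theta (4-7 Hz) and alpha (8-11 Hz) rhythms,
    Mahalanobis-distance deviation of per-epoch band spectra from an
    alert-state baseline, a weighted combined fatigue statistic, ROC-based
    threshold calibration with a Youden operating point, and an alarm-emitting
    monitor. Also provides a synthetic EEG and trial-series generator for
    validation, and phase-segmented least-squares analysis of learning-curve
    trial data (errors, completion time, perceived fatigue).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
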