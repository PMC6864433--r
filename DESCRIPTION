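Package: fatiguecps
Title: Running-Fatigue Classification from Surface EMG via Lactate
    Change-Point Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying running fatigue from multichannel surface
    electromyography (sEMG). Implements zero-phase Butterworth band-limiting,
    envelope-based muscle-burst detection and stride-cycle assembly, per-burst
    spectral descriptors (distributive power frequencies, band powers) and
    per-stride timing features (phase shifts, active-time percentages, cycle
    RMS, right-left asymmetries), connected three-segment piecewise-linear
    change-point segmentation of sparse blood-lactate curves into aerobic,
    anaerobic and recovery phases, Spearman-threshold feature selection, and
    random-forest classification/regression with out-of-bag ROC/AUC and
    Kruskal-Wallis validation. Includes a synthetic-session generator with
    known ground truth so every pipeline stage is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
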