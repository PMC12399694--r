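Package: fwamp
Title: Fibrillatory-Wave Amplitude Analysis of Surface ECGs in Atrial
    Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Pipeline for estimating fibrillatory-wave amplitude (fWA) from
    multi-lead surface ECGs recorded during atrial fibrillation, and for
    relating amplitude changes across a catheter-ablation procedure to
    long-term rhythm outcome. Includes 1-50 Hz preconditioning, beat
    detection and single-beat QRST cancellation, envelope-based per-lead
    fWA estimation with 12-lead aggregation, synthetic 12-lead AF ECG and
    cohort generators with known ground truth, first-principles cohort
    statistics (Mann-Whitney U, Fisher/chi-squared, ROC with
    sensitivity+specificity-optimal cutoffs, univariate logistic odds
    ratios, Kaplan-Meier and log-rank), and a two-threshold decision rule
    on mean fWA and its relative decrease.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    pROC,
    jsonlite
Config/testthat/edition: 3
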