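Package: ecgaf
Title: Atrial Fibrillation Screening from Single-Lead ECG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete pipeline for classifying short single-lead
    electrocardiogram (ECG) recordings into Normal sinus rhythm, atrial
    fibrillation (AF), Other arrhythmia, and Noisy classes. Includes a
    seeded synthetic ECG generator (normal sinus rhythm, AF, and
    noise-dominated segments with ground truth), readers and writers for
    WFDB and Challenge-style single-lead records, 30-second segmentation
    from rhythm annotation tracks, Butterworth band-pass filtering and
    adaptive-threshold R-peak detection, a 31-dimensional hand-crafted
    feature set (Lorenz-plot AF evidence, delta-RR Shannon entropy,
    Kolmogorov-Smirnov statistic against an AF reference distribution,
    average-beat and per-beat wave morphology, RR-interval statistics,
    and signal-quality indices), gradient-boosted multiclass
    classification with Matthews-correlation-guided cross-validation and
    importance-based feature selection, and Challenge-style evaluation
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    xgboost,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
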