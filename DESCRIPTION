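Package: bpbench
Title: Benchmarking Framework for PPG-Based Cuffless Blood Pressure Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and auditing machine-learning benchmarks for
    non-invasive blood pressure estimation from the photoplethysmogram (PPG).
    Provides a synthetic paired PPG/arterial-pressure cohort generator with
    controllable morphology, skewed blood-pressure distributions, per-subject
    correlation and injectable artifacts; a staged signal-cleaning pipeline
    (cross-correlation alignment, fixed-length segmentation, pressure-range and
    heart-rate filters, cycle detection, distortion screening, cubic-spline
    baseline-wander removal, skewness signal-quality rejection) with an audit
    trail; a handcrafted PPG/VPG/APG feature catalog (landmark amplitudes,
    elapsed times, areas, widths, spectral, histogram, slope-deviation, quality
    and aging-index features) with tree-ensemble feature selection;
    subject-grouped iterative multi-label stratified splitting with leakage
    audits; mean-absolute-scaled-error (MASE) centred evaluation with
    pooled-fold metrics and bootstrap model comparison; and an orchestration
    harness with a reference model zoo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    e1071,
    xgboost,
    nnet,
    jsonlite,
    withr,
    signal
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
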