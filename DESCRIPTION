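Package: ptcscreen
Title: Drug-Response Scoring and Clinical Concordance for Patient-Derived
    Tumor-Like Cell Cluster (PTC) Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based quantification and drug-response analysis for
    patient-derived tumor-like cell cluster (PTC) screening assays.
    Segments clusters in brightfield well images, measures areas in
    physical units with a minimum-diameter filter, scores viability as
    the ratio of summed cluster areas between baseline and endpoint
    wells with negative-control quality control and a fixed efficacy
    cutoff, calibrates per-drug testing concentrations against clinical
    objective response rates, quantifies replicate reproducibility
    (coefficient of variation and pair-resampling correlations), and
    evaluates concordance with RECIST clinical outcomes (contingency
    tables, accuracy, Mann-Whitney tests, ROC/AUC with DeLong or
    bootstrap confidence intervals, Fisher's exact test, waterfall
    summaries). Includes a seeded synthetic-data generator for wells,
    images, drug panels and cohorts so the full pipeline is testable
    without raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
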