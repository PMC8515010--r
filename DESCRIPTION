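Package: digitalMarker
Title: Transcriptome-Screened Digital Markers for Rapid Chemotherapy Sensitivity Prediction
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens whole-transcriptome TPM profiles with cancer-type and
    drug-specific filters (expression level, correlation with IC50 Z-scores,
    univariate Fisher linear discriminant between IC50 extremes, Mann-Whitney
    ranking for labelled patient cohorts) to build compact "digital marker"
    gene lists; selects the marker size and K-nearest-neighbour hyperparameters
    by 5-fold cross-validated enumeration; predicts drug sensitivity for new
    samples from RNA-seq TPM or qRT-PCR delta-Cq input via a linear
    delta-Cq-to-TPM calibration; and emits per-drug recommendations from
    relative IC50 Z-scores. Includes synthetic-data generators with planted
    sensitivity-associated genes so every stage is testable without external
    pharmacogenomic downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
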