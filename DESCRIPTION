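Package: sigtransfer
Title: Interpretable Gene-Signature Classifiers and Cross-Dataset
    Transferability for Single-Cell Disease-State Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains small symbolic gene-signature classifiers (add/multiply
    expression trees behind a logistic link) of per-cell disease state for
    each cell type of a single-cell RNA-seq dataset, transfers them to other
    datasets sharing that cell type, and quantifies transfer with a
    transferability-corrected performance score based on precision-recall
    AUC. Includes a negative-binomial multi-dataset cohort simulator with
    planted per-cell-type signatures and batch effects, an evolutionary
    structure search with random sampling, precision-recall and ROC metrics,
    median-conditioned response surfaces, and a tabular transfer report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
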