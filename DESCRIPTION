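Package: fusion6mA
Title: Feature-Fusion Prediction of DNA N6-Methyladenine Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts DNA N6-methyladenine (6mA) sites in fixed-length
    genomic windows centered on an adenine. Four sequence feature encoders
    (one-hot binary, nucleotide chemical property, k-mer composition, and
    position-specific first-order Markov transition log-ratios) are fused
    after per-block tree-importance feature selection and min-max
    normalization, and classified with a radial-basis-function support
    vector machine tuned by power-of-two grid search. Includes
    confusion-based evaluation (sensitivity, specificity, accuracy,
    Matthews correlation coefficient), ROC/AUC, stratified k-fold
    cross-validation with full per-fold refitting, a Markov-chain
    log-likelihood-ratio baseline classifier, and a synthetic benchmark
    generator with class-conditional transition structure and an exact
    Bayes-accuracy calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    e1071,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
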