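Package: succnet
Title: Hybrid Convolutional and Language-Model-Embedding Prediction of Lysine Succinylation Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts lysine succinylation sites from protein sequence windows using
    a lightweight hybrid neural network: a learned amino-acid (word) embedding
    processed by a one-dimensional convolutional branch (plain, inception, or
    residual-concatenation variants) combined with a multilayer-perceptron branch
    over a pretrained protein-language-model embedding of the target residue.
    Includes window extraction and encoding from FASTA input, balanced dataset
    construction by random undersampling, stratified splits and imbalanced
    validation-set construction, end-to-end and branched-frozen training with
    Adam and binary cross-entropy, ten-fold cross-validation, a full suite of
    binary-classification metrics with ROC and precision-recall curves,
    feature-group selection by per-group PCA, minimum-redundancy maximum-relevance
    selection and gradient-boosting importance, exact and kernel Shapley
    attribution of window positions with sequence-position and structural-distance
    aggregation, and a synthetic-data generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
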