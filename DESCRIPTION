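Package: sucstack
Title: Lysine Succinylation Site Prediction with Fused Sequence Features
    and a Stacking Ensemble
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts lysine succinylation sites in protein sequences from
    21-residue peptide windows. Five sequence encoders (grouping-weight
    profiles, one-hot, CBOW k-mer embeddings, chaos-game representation of
    reverse-translated codons, and Haar-wavelet summaries of physicochemical
    profiles) are fused into an 811-dimensional feature vector, reduced by
    LASSO, and classified by a two-layer stacking ensemble whose base
    learners are a linear SVM, a broad learning system, and gradient-boosted
    trees, combined by a logistic meta-learner that also sees the selected
    original features. Includes a synthetic peptide generator, stratified
    cross-validation with Sn/Sp/Acc/MCC/F1/AUC reporting, encoder ablation
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    e1071,
    glmnet,
    jsonlite,
    seqinr,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
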