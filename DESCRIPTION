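Package: methylstack
Title: Stacked Ensemble Prediction of RNA 5-Methylcytosine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA 5-methylcytosine (m5C) modification sites from
    fixed-width cytosine-centered sequence windows. Encodes windows with
    eleven nucleotide descriptor families (NAC, Kmer, CKSNAP, ENAC, NCP,
    DBE, PS2, Z-curve, mismatch profile, MMI, ASDC), trains a grid of base
    classifiers over every encoder/algorithm pair, and combines them by
    out-of-fold stacking with a random-forest meta-classifier or by
    hard/soft voting. Includes evaluation utilities (accuracy, sensitivity,
    specificity, F1, Matthews correlation, ROC/AUC, cross-validation,
    cross-species transfer matrices, paired significance tests on absolute
    prediction error), model interpretation (Shapley-value feature
    attribution and t-SNE embedding of base-model probabilities), and a
    synthetic motif-based data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    class,
    e1071,
    glmnet,
    MASS,
    nnet,
    randomForest,
    ranger,
    rpart,
    xgboost,
    jsonlite,
    Biostrings
Suggests:
    pROC,
    yaml,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
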