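Package: aptaboost
Title: Aptamer and Protein-Aptamer Interaction Prediction from Sequence
    Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts whether a nucleotide sequence is an aptamer and
    whether a protein-aptamer pair interacts, from sequence-derived
    physicochemical features. Implements five protein encoders (amino acid
    composition, pseudo amino acid composition, grouped amino acid
    composition, CTD composition, sequence-order-coupling number), three
    nucleotide encoders (nucleotide composition, pseudo k-tuple nucleotide
    composition, normalized Moreau-Broto autocorrelation), SMOTE minority
    oversampling of the training partition, and an AdaBoost ensemble whose
    base learners are random forests. Includes construction of a
    structure-screened negative aptamer set via dot-bracket statistics and
    a built-in maximum-base-pairing folder, plus a full evaluation suite
    (confusion metrics, ROC/AUC, DeLong's paired AUC test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ranger,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
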