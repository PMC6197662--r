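Package: xylanact
Title: Predicting Xylanase Activity and Halo Class from Pseudo Amino Acid
    Composition Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-activity modelling for glycoside hydrolase family 11
    (GH11) xylanases. Extracts amphiphilic Pseudo Amino Acid Composition
    (PseAAC) feature vectors from amino-acid sequences, classifies the halo
    zone produced on xylan screening plates into low/medium/high classes, and
    regresses enzyme specific activity (IU per ml) under fixed pH and
    temperature conditions. Models (k-nearest-neighbour, linear-kernel support
    vector machines, random forests, AdaBoost.R2 regression trees, Gaussian
    naive Bayes) are evaluated with stratified 10-fold cross-validation and the
    jackknife (leave-one-out) test on pooled out-of-fold predictions. Includes
    a transcription of the study's 41-strain Bacillus subtilis screening table
    and a synthetic-data generator so the whole pipeline is testable without
    wet-lab data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
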