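Package: gepdx
Title: Gene Expression Programming Diagnostics for Serum Tumor-Marker Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evolutionary binary classification of small cell lung cancer
    from routine serum biochemistry. Implements a gene expression programming
    (GEP) engine over karva-notation chromosomes (breadth-first expression-tree
    decoding, random numerical constants, the canonical genetic operators,
    roulette-wheel selection with elitism and an accuracy fitness), two
    published evolved classifiers over the six-marker panel LDH, CRP, sodium,
    chloride, CEA and NSE, a train/test evaluation pipeline with the full
    confusion-matrix and score-regression metric panel plus ROC analysis,
    univariate cohort statistics (tie-corrected Mann-Whitney, Pearson
    chi-square, two-sample t, Spearman correlation), and a calibrated
    synthetic cohort generator so the whole pipeline runs without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
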