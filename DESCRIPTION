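Package: pathomsi
Title: Microsatellite Instability Prediction from Histopathology by Ensemble
    Patch Likelihood Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts slide-level microsatellite status (MSI vs MSS) from
    haematoxylin-eosin whole-slide images under multiple-instance learning.
    A compact convolutional patch discriminator trained with slide-label
    inheritance emits per-patch MSI likelihoods; two bag-level aggregators
    summarise each slide - a patch-likelihood histogram classified with
    gradient-boosted trees (PALHI) and a TF-IDF bag-of-words representation
    classified with Gaussian naive Bayes (BoW) - and their convex ensemble
    (EPLA) gives the final slide score. Includes ROI polygon parsing and
    tiling with an overlap filter, ROC/AUC inference (DeLong intervals,
    paired Wald tests, Youden cutoffs), cross-cohort transfer by
    fine-tuning, permutation importance of the slide-level signatures,
    genomic and transcriptomic association scores (TMB, INDEL load,
    pathway deficiency, CYT, CD8 T-effector), and synthetic cohort
    generators that exercise the full pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    xml2,
    jsonlite,
    yaml,
    withr,
    png,
    xgboost,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
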