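Package: massContext
Title: Context-Ensemble Classification of Breast Masses in Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies segmented breast masses on mammograms as benign or
    malignant by ensembling one convolutional network over multiple
    context-diverse regions of interest (ROIs). Implements scale-based and
    translation-based multi-context ROI extraction, contrast enhancement
    (histogram equalization, unsharp masking, median filtering),
    multi-context/multi-orientation/multi-scale training augmentation, a
    ResNet-50 backbone and four breast-density-specific architectural
    variants with global average/max pooling fusion and projection
    shortcuts, decision fusion by majority/soft/max voting or stacked
    generalization with an SVM meta-classifier, and screening metrics
    (sensitivity, specificity, accuracy, Cohen's kappa, F1, AUC) including
    reconstruction of integer confusion matrices from published rates. A
    synthetic lesion-phantom generator makes the full pipeline runnable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    e1071,
    randomForest,
    png,
    tiff,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    caret,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
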