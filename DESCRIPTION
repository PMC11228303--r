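Package: fusionrad
Title: Hybrid Radiomics and Deep-Feature Fusion for Brain-MRI Tumor Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for binary tumor classification of gray-level MRI images and
    volumes by fusing hand-crafted radiomics texture features (first-order,
    absolute-gradient, GLCM, GLRLM and GLSZM statistics over a region of
    interest) with deep features from a compact multi-scale residual
    convolutional network (Seq-ResNet blocks with transpose-convolution
    up/down-sampling).  Includes BraTS-style preprocessing (background
    cropping, non-zero z-scoring, foreground one-hot channel, median and soft
    weighted median filtering), training-time augmentation, a multi-kernel
    support vector machine classification head with stratified k-fold
    cross-validation, evaluation metrics (precision, recall, F-measure,
    average precision, ROC/AUC), and a synthetic texture-phantom generator so
    the entire pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    jsonlite,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
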