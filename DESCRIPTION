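Package: histoscore
Title: Histology Tile Classification and Prognostic Scoring for Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline from haematoxylin-and-eosin style slide
    images to a prognostic risk score. Provides a synthetic six-class slide
    generator with ground truth, Otsu tissue masking, fixed-grid tiling,
    Reinhard colour-transfer stain standardization with tissue-masked
    statistics, a pluggable six-class tile classifier, classification-map
    smoothing and representative-tile selection, per-slide pathological
    signature extraction (colour, texture, morphometry, composition), LASSO
    penalized Cox feature selection with histological and combined risk
    scores, a maximally selected log-rank cutpoint, and survival model
    evaluation (Kaplan-Meier, log-rank, Cox regression, Harrell's C-index,
    time-dependent ROC with censoring weights, calibration, and continuous
    net reclassification improvement).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    survival,
    glmnet,
    ranger,
    nnet,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
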