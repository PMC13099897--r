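Package: wsimil
Title: Multiple-Instance Learning for Whole-Slide Image Recurrence-Risk Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for three-tier recurrence-risk stratification of
    hematoxylin-and-eosin whole-slide images (WSIs): saturation-channel tissue
    segmentation and non-overlapping patch extraction, pluggable patch-feature
    encoding into per-slide instance bags, three attention-based
    multiple-instance-learning slide classifiers (a single-branch
    clustering-constrained attention model with gated attention and a GELU
    two-layer classifier head, a gated multi-head attention model with
    class-specific attention distributions, and an attention-pooling plus
    gradient-boosted-tree pipeline with a 23-dimensional enhanced feature
    vector), class-imbalance-aware losses (focal loss, label smoothing,
    weighted cross-entropy), patient-level stratified cross-validation with
    per-fold metric aggregation, attention heatmap rendering, and a synthetic
    bag/slide generator so the whole stack is exercisable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    EBImage,
    png,
    yaml,
    xgboost,
    nnet,
    pROC,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
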