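Package: pneunet
Title: Lightweight Convolutional Network for Pneumonia Detection on Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds, trains and audits a lightweight convolutional neural
    network for binary pneumonia detection on frontal chest radiographs. The
    architecture combines depthwise-separable feature fusion, squeeze-and-
    excitation channel attention, atrous spatial pyramid pooling and a
    trainable spatial-attention pooling head, all implemented as vectorized
    R with reverse-mode gradients, so every block has a numeric contract
    testable without a deep-learning framework. Includes stratified data
    splitting, a seed-controlled synthetic radiograph generator for offline
    testing, the full optimization recipe (Adam, binary cross-entropy with
    L2 weight decay, dropout, early stopping with best-checkpoint selection),
    evaluation statistics (confusion matrix, per-class precision/recall/F1,
    ROC/AUC, McNemar's paired test) and Grad-CAM saliency maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    jpeg,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
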