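Package: endossl
Title: Multi-Task Self-Supervised Learning for Endoscopic Frame Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised representation learning for upper-gastrointestinal
    endoscopy frames. Implements three pretext tasks (grayscale colorization,
    masked center-patch prediction, and jigsaw permutation classification)
    trained on convolutional autoencoders, fusion of the pretrained encoders
    into a downstream classifier for three anatomical landmark classes
    (Z-line, esophageal, antrum/pylorus), attention and transformer model
    variants, the full training and regularization protocol (SMOTE class
    balancing, augmentation, dropout, early stopping), patient-wise
    leakage-free data splitting, classification metrics with one-vs-rest
    ROC/AUC, and Grad-CAM saliency maps. Includes a synthetic endoscopy-like
    image generator so every stage is runnable and testable without access
    to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    pROC
Config/testthat/edition: 3
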