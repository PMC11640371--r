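Package: fundusfusion
Title: Multi-Disease Retinal Fundus Image Classification with Fluorescence-Simulation Preprocessing and Dual-Backbone Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully reproducible pipeline for five-class retinal
    fundus image classification (normal, diabetic retinopathy, hypertensive
    retinopathy, glaucoma, and contrast/cataract-type haze). Implements a
    deterministic fluorescence-simulation preprocessing transform (green-channel
    amplification, blue-channel suppression, optional HOT colormap), an
    AutoAugment-style training-set augmentation and class-balancing policy,
    frozen convolutional feature extractors in the MobileNetV2 and
    EfficientNetB0 block styles with global average pooling, a feature-fusion
    dense classification head with batch normalization, a gradient-boosted-tree
    head on deep features, Grad-CAM saliency maps, multiclass evaluation
    (confusion matrix, sensitivity, specificity, F1), and a seeded synthetic
    fundus-image generator so the whole pipeline is testable end to end
    without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    optparse
Config/testthat/edition: 3
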