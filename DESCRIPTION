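Package: camtrapdetr
Title: Transformer-Based Detection of Wildlife in Camera-Trap Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A set-prediction (DETR-family) object detector for camera-trap
    wildlife imagery, built around three architectural components: a
    multi-channel coordinate attention mechanism that pools feature maps
    along height, width and channel directions; a multi-dimension feature
    aggregation module fusing shallow, intermediate and deep pyramid levels
    through re-parameterizable convolution blocks; and a lightweight
    GELAN-style terminal backbone stage replacing the last ResNet-18 layer.
    Includes the composite VariFocal/GIoU/L1 training objective with
    Hungarian matching, COCO-style mAP evaluation, a deterministic synthetic
    camera-trap scene generator (occlusion, blur, night regimes, mosaic
    augmentation, 7:2:1 splits), and a small pure-R tensor layer with
    reverse-mode differentiation so toy models can be trained and evaluated
    on CPU without an external deep-learning framework.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
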