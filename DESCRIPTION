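Package: palmdetr
Title: NMS-Free Transformer Detection of Crop Health in UAV Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for detecting individual plant crowns and their health status
    in overhead UAV imagery of plantations. Implements the bespoke components of
    a hybrid YOLO/RT-DETR detector: the SIMIoU bounding-box regression loss
    family (IoU, GIoU, EIoU, SIoU, inner-IoU and the powered corner-distance
    composite), structurally re-parameterizable diverse-branch convolution
    blocks that collapse to a single 3x3 convolution at deploy time, CARAFE
    content-aware upsampling and channel-enhancement (FEM/FSM) feature
    operators, a query-based NMS-free encoder-decoder detector with Hungarian
    set matching, COCO-style mAP evaluation, and a deterministic synthetic
    plantation-scene generator so the whole pipeline runs on CPU without
    external data. Includes a small reverse-mode automatic differentiation
    engine so training runs in plain R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
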