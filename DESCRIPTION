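Package: germkit
Title: Seed Germination Vigor Phenotyping from Time-Lapse Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A GPU-free toolkit for assessing seed germination vigor under
    salt stress from time-lapse tray imagery. Implements the IoU family of
    bounding-box regression losses (IoU, GIoU, DIoU, CIoU, EIoU and the
    combined ECIoU), a gradient-descent box-fitting harness for comparing
    their convergence, the forward pass of the coordinate-attention block,
    object-detection evaluation (greedy matching, non-maximum suppression,
    precision/recall/AP/mAP), germination-vigor phenotyping (germination
    rate, germination index, root length from the detection-box diagonal),
    dataset construction utilities (Pascal-VOC XML to YOLO txt conversion,
    box-aware augmentation, train/validation/test splitting, acquisition
    scheduling), and a synthetic time-lapse generator with a classical
    reference detector so the whole pipeline runs end to end without any
    trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    xml2,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Software, Phenotype, Visualization
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'boxgeom.R'
    'coordatt.R'
    'dataset.R'
    'deteval.R'
    'phenotype.R'
    'simulate.R'
    'render.R'
    'detect.R'
    'germkit-package.R'
    'regression.R'
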