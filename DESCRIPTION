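Package: podrot
Title: Detection and Severity Grading of Peanut Pod Rot from RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-vision grading of peanut pod rot severity. Implements a
    compact YOLOv5s-style one-stage detector with Shuffle Attention blocks
    inserted after each backbone C3 stage and EIoU bounding-box regression in
    place of CIoU, trained and run entirely on CPU at reduced scale. Includes
    Pascal VOC XML / YOLO txt annotation I/O with the standard augmentation
    primitives, detection evaluation (precision, recall, AP/mAP at IoU 0.5,
    image-level comparison precision, k-fold splits), a grade-classification
    module converting per-image pod counts into a rotten pod rate and a
    five-level disease grade, and a synthetic scene generator emulating pod
    clusters under three adhesion conditions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Rcpp,
    xml2,
    png,
    yaml,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
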