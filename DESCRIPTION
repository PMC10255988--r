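Package: pigback3d
Title: Individual Pig Identification from Overhead Back-Surface Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Two-stage individual identification of fattening pigs from
    overhead 3D scans. A PointNet++-style part-segmentation model separates
    the animal's back surface from the ground and head, and a point-cloud
    classifier with local-global grouping (LGG) -- multi-scale ball-query
    neighbourhoods augmented with a per-sample adaptive global radius taken
    from the farthest-point-sampled centroids -- assigns the individual
    identity. Includes a synthetic overhead-scan generator (parametric back
    surface, occlusion shadow, sensor noise, surface cracks), depth-frame to
    point-cloud conversion under a pinhole model, PLY/PCD readers and
    writers, farthest point sampling and grouping kernels, training with
    Adam on a negative log-likelihood loss, and confusion-matrix based
    evaluation metrics (accuracy, precision, recall, F1, IoU, mIoU).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
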