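Package: wheatrecon
Title: Data-Driven 3D Reconstruction and Phenotyping of Wheat Plants from
    Organ-Labelled Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the three-dimensional morphological structure of
    single wheat plants from organ-labelled point clouds and extracts 18
    plant-morphology parameters. Tiller axes are repaired and traced by
    height-slab slicing, density-based clustering and a scored top-down
    search; leaf skeletons are extracted by k-means segmentation, endpoint
    detection and nearest-neighbour chaining; leaf bases are located and
    corrected against the tiller skeletons and assembled into a phytomer
    model. Includes a procedural synthetic wheat-plant generator with known
    ground truth emulating multi-view-stereo artifacts, labelled point-cloud
    I/O (ASCII PLY and per-instance text directories), voxel downsampling,
    smallest-enclosing-circle girth, convex-hull ear volume, and evaluation
    metrics (per-class accuracy and IoU, instance average precision, recovery
    R-squared and RMSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
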