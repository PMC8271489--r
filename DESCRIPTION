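Package: pldm
Title: Plant Location-Distribution Mapping from Aerial Orchard Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts per-pixel vine segmentation masks of trellised-orchard
    aerial imagery into gradient canopy-distribution maps by resampling
    normalization: masks are tiled at a sampling size S, each tile is replaced
    by its vine-pixel ratio R, and the ratio grid is rendered as a four-class
    gradient map or binarized at one of eight threshold levels T. The
    sampling-size/threshold pair is optimized by intersection-over-union
    against ground-truth canopy ranges, and detected plant locations are fused
    onto the distribution map. Includes a synthetic trellised-orchard scene
    generator with ground truth, baseline per-pixel classifiers (excess-green
    thresholding, random forest, RBF support vector machine), tiling and
    stitching of large orthomosaics, and segmentation-quality metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    randomForest,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
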