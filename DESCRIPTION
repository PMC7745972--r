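Package: plantgantry
Title: Simulated Gantry Imaging and Automatic Labeling of Plant Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully software-simulated gantry-camera rig for generating
    labeled plant-image datasets. A virtual pan-tilt camera moves through a
    cuboid travel volume, images parametric plants placed at marked floor
    positions against a blue keying background, and labels each plant
    automatically from known geometry: the world-to-camera-to-image transform
    chain projects per-plant bounding spheres to image-space bounding boxes,
    subimages are cropped and written with a JSON metadata record per master
    image. Includes a serpentine (nested zig-zag) route planner with a
    trapezoidal stepper-motion timing model, production-rate accounting,
    CIELAB chroma-key segmentation with morphological cleanup and background
    replacement or subtraction, and evaluation statistics (class weights,
    binomial accuracy and standard error, Clopper-Pearson intervals, dataset
    summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
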