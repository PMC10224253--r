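Package: canopyseg
Title: Machine-Learning Segmentation of Plant Canopy Images and SPAD Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pixel-wise segmentation of glasshouse and field plant images for
    high-throughput phenotyping. Converts 8-bit RGB images into a 24-channel
    multi-color-space feature stack (RGB, HSV, YCbCr, Lab, YUV, Luv, HLS, XYZ),
    ranks channels by decision-tree recursive feature elimination, and trains
    pixel classifiers (a single-hidden-layer perceptron trained by
    backpropagation, random forests, and support vector machines) that are
    compared against excess-green (ExG) and excess-green-minus-red (ExGR)
    index baselines with Otsu thresholding. Segmentations are scored with the
    Qseg, Sr and Es quality factors, color vegetation indices are extracted
    from segmented regions, and chlorophyll (SPAD) values are predicted from
    the top-correlated indices with gradient-boosted regression trees. A
    seeded synthetic-scene generator provides ground-truth masks, labeled
    patch sets and SPAD-linked cohorts so the whole pipeline runs without
    external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    rpart,
    ranger,
    e1071,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
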