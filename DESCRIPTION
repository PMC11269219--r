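Package: radiclemetry
Title: Radicle Morphometry from Instance Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for measuring embryonic-root (radicle) length in seed
    germination imagery from per-seed binary segmentation masks. Implements
    instance-mask merging to a single binary image, a from-scratch Canny edge
    chain (Gaussian smoothing, Sobel gradients, non-maximum suppression,
    double-threshold hysteresis), half-perimeter length estimation with
    physical calibration (cm per pixel), per-seed time-series tracking and
    growth-rate analysis on tray layouts, the numeric forward pass of a
    multi-scale convolutional attention (MSCA) block, and evaluation
    arithmetic (average precision over IoU thresholds, convolution
    FLOPS/parameter counts, machine-vs-manual agreement regression). Includes
    a synthetic radicle generator with exact ground-truth centerline arc
    lengths so the whole chain is testable without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
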