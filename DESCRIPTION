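Package: micov
Title: Microbial Surface Coverage Quantification for Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of microbial surface coverage in
    multi-channel confocal z-stack images of microorganisms co-localized with
    human cells on implant surfaces. Implements maximum-intensity projection,
    flatfield correction and percentile contrast stretching; label-mask algebra
    (connected components, ROI area filtering, region subtraction, dual-mask
    combination, tiling); three triaged coverage-quantification methods with a
    pluggable segmenter-backend contract; an instance-segmentation evaluation
    suite (pixel accuracy, IoU, object matching, average precision, size-
    stratified reports); and a seeded generator of synthetic confocal-like
    scenes with ground-truth masks for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    png,
    yaml,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
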