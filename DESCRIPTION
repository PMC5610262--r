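Package: isletrace
Title: Clonal, Volumetric, Calcium and Spatial Analysis of Multicolor-Labeled Pancreatic Islets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multicolor (Brainbow-style) lineage
    tracing of zebrafish pancreatic beta-cells. Implements equivalence-test
    (TOST) clustering of per-cell RGB color signatures into clones,
    threshold-and-label 3D volumetry with volume-ratio cell-number
    estimation, background recombination probability arithmetic, GCaMP
    calcium-trace normalization and glucose-responder classification, and
    anterior/posterior islet asymmetry statistics. Includes a synthetic-data
    generator that simulates Cre-lox cassette recombination, clonal growth,
    voxelized image stacks and calcium traces with full ground truth, so
    every stage can be validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    igraph,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ggplot2,
    rlang,
    withr,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
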