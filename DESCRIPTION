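Package: mitonet
Title: Mitochondrial Network Morphology Metrics and Fission-Fusion Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the topology of mitochondrial networks from
    fluorescence micrographs (binarization, skeletonization, conversion of
    the skeleton to a pixel graph, and computation of mean degree, giant
    cluster, loop, branch and cluster size distributions) and simulates the
    network with an agent-based Gillespie model of reversible tip-to-tip and
    tip-to-side fission-fusion reactions on a fixed number of unit edges.
    Fusion-to-fission rate ratios are inferred by scanning the two-parameter
    phase space and matching observed summary statistics.  A synthetic
    micrograph generator renders ground-truth filament networks so the whole
    pipeline is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    tiff,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
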