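Package: smlmtopo
Title: Spatial Statistics and Persistent-Homology Topology for
    Single-Molecule Localization Microscopy Point Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing single-molecule localization microscopy
    (SMLM) coordinate tables of cell nuclei: Monte Carlo simulation of
    homogeneous, clustered and two-channel point patterns; Ripley-type
    pairwise-distance frequency histograms with linear-slope and
    cluster-peak decomposition; density-based (DBSCAN-style) nano-cluster
    detection with convex-hull geometry computed by the surveyor's
    (shoelace) formula; Vietoris-Rips sphere-growth filtrations with
    dimension-0/1 persistence barcodes and Betti numbers; and Jaccard-index
    barcode similarity with heterochromatin-association classification of
    DNA-damage repair clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
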