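Package: epimcs
Title: Cell Tracking in Epithelial Sheets via Maximum Common Subgraphs
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tracks cells between consecutive frames of segmented
    live-imaging data of epithelial sheets. Each frame is represented as a
    polygonal tessellation and its dual cell-adjacency network; consecutive
    frames are aligned by seeded, iterative construction of a maximum common
    subgraph between the two networks, followed by cleaning and
    adjacency-guided post-processing that resolves neighbour exchanges
    (T1 transitions), cell removals (T2 transitions) and cell divisions.
    Includes conversion of 16-bit label images to polygonal tessellations,
    an in-silico tissue generator based on Lloyd-relaxed Voronoi
    tessellations with perturbation operators, and sequence-level tracking
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    igraph,
    deldir,
    jsonlite,
    tiff,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllGenerics.R'
    'AllClasses.R'
    'epimcs-package.R'
    'tissue-mesh.R'
    'mcs-core.R'
    'event-resolution.R'
    'geometry-utils.R'
    'segmentation-io.R'
    'statistics.R'
    'synthetic-tissue.R'
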