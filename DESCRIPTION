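Package: d3k
Title: Dissimilarity-Density-Dynamic-Radius K-Means Clustering for
    Single-Cell Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic K-means initialisation for single-cell
    RNA-seq expression matrices. Builds a range-normalised L1
    dissimilarity matrix, derives a dynamic neighbourhood radius from a
    fitted linear model of the dissimilarity summary statistics, and
    selects initial cluster centers by iteratively maximising a
    density/compactness/separation weight; the number of clusters
    emerges from the selection loop rather than being fixed in advance.
    Includes seeded Lloyd refinement, external evaluation metrics (NMI,
    pairwise F-measure, optimally mapped accuracy, Rand index),
    synthetic-data generators (Gaussian blobs with uniform background
    noise; negative-binomial count matrices with marker-gene blocks and
    dropout), and readers/writers for delimited and Matrix Market
    expression files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rtsne,
    clue,
    jsonlite,
    methods,
    tools,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
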