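Package: stromalcensus
Title: Single-Cell Stromal Census and Traction Force Cytometry for Fibrotic Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for building a single-cell census of fibrotic stromal tissue
    and for measuring single-cell contractility on elastic substrates. Covers
    droplet scRNA-seq quality control and library-size log-normalization,
    variable-gene selection, PCA with permutation parallel analysis, shared
    nearest-neighbour Louvain clustering with Wilcoxon marker statistics,
    binned control-gene module scoring, and diffusion-map / principal-curve
    pseudotime for the myofibroblast activation continuum. A traction force
    cytometry arm provides particle image velocimetry, Fourier-transform
    traction reconstruction on an elastic half-space, and single-cell force
    signature embedding. Ground-truthed synthetic data generators make the
    whole pipeline testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    withr,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
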