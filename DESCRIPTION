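Package: metacellr
Title: Scalable Metacell Partitioning of Single-Cell RNA-Seq UMI Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions large sparse single-cell RNA-seq UMI count matrices
    into metacells: disjoint groups of cells that can be treated as repeated
    sparse samples from one multinomial transcriptional state. Implements a
    recursive divide-and-conquer driver over balanced K-nearest-neighbour cell
    graphs, a two-sided stability score for graph partitioning with direct
    control over metacell sizes, adaptive deviant (outlier) cell detection,
    and a rare-gene-module pre-process that preserves cell states present in
    as little as 0.01% of the data. Ships quality-control metrics (inner
    normalized variance, rare-behavior AUROC screens), a ground-truthed
    synthetic data generator, 10x-style Matrix Market and AnnData-layout
    HDF5 input/output, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    igraph,
    tibble,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
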