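Package: heatomics
Title: Multi-Omics Analysis of Algal Heat-Stress Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing paired transcriptome-proteome time courses
    of Chlamydomonas reinhardtii heat-stress experiments run in turbidostatic
    photobioreactors. Covers count filtering, TPM normalization, negative
    binomial differential-expression calls with a three-criterion
    significance rule, surprisal (SVD constraint) decomposition,
    median-of-ratios proteome normalization with kNN-plus-Gaussian missing
    value imputation and Dunnett testing, random-matrix-theory thresholded
    correlation networks with module eigenvectors and ontology-expanded
    hypergeometric enrichment, windowed transcript-protein fold-change
    correlation, and calculators for growth rate, pigments, qPCR
    fold-change, ROS, chlorophyll fluorescence, electrochromic shift, P700
    kinetics, 77K spectra, oxygen evolution, and flow-cytometry DNA-content
    ploidy. A synthetic-data generator emulates the statistical structure of
    the assays so every stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    igraph,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    DESeq2,
    multcomp
Config/testthat/edition: 3
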