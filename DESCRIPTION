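Package: tfhscreen
Title: Design, Simulation and Analysis of In Vivo Pooled CRISPR Screens of
    Tfh Differentiation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for targeted in vivo pooled CRISPR knockout screens of
    CD4 T cell differentiation read out by cell sorting. Covers sgRNA
    library construction and cloning-oligo assembly, a generative forward
    model of the screen (plasmid pool, in vitro culture, adoptive-transfer
    engraftment bottleneck, in vivo expansion, Tfh/Th1 bifurcation,
    sorting, and amplicon sequencing) with known ground truth, spacer
    extraction and counting from amplicon FASTQ, hierarchical
    replicate-averaged log2 fold changes with control-anchored Z-scores
    and alpha-RRA permutation false-discovery rates, quadrant hit
    classification, and Monte-Carlo spike-in power analysis of the
    assay's detection limits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    Biostrings,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: CRISPR, PooledScreens, FunctionalGenomics, Software
RoxygenNote: 7.3.3
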