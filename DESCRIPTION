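Package: gleam
Title: Gene-Set Gain and Loss Evolution Analysis and Mapping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of functional gene sets
    (e.g. flagellar motility or peptidoglycan biosynthesis gene repertoires)
    across a genome phylogeny. Given a rooted tree and a genome-by-gene
    occurrence matrix with explicit missing data, gleam performs per-gene
    ancestral character state reconstruction (Fitch parsimony on cladograms,
    or a two-state Mk model with Felsenstein pruning, rate fitting and
    marginal posteriors), classifies gene-set states at every node by a
    core-set presence rule, and calls consensus full or partial gain and
    loss events on branches where individual gene reconstructions agree.
    Genomic co-location of set genes is summarised as synteny clusters from
    GFF3 or tabular coordinates. A deterministic synthetic-data generator
    (Yule trees, binary gain/loss gene histories, forced loss scenarios,
    genome incompleteness, toy genome layouts) makes the whole pipeline
    testable at desk scale, including exhaustive-enumeration oracles for
    the parsimony and likelihood machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    S4Vectors,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
biocViews: Phylogenetics, ComparativeGenomics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
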