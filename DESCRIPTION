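Package: wgdsig
Title: Detecting Whole-Genome Duplication Signatures from Paralog Ages,
    Co-Linearity and Gene Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to decide whether the gene-duplicate complement of a
    genome bears the signature of whole-genome duplication (WGD) rather
    than continuous small-scale duplication or bursts of segmental
    duplication. Implements node-weighted synonymous-distance (Ks) age
    distributions from Markov-clustered paralog families with pairwise
    Ks estimated under the Goldman-Yang codon model, chaining of
    within-genome homolog hits into co-linear blocks with topology
    classification (inter-scaffold, tandem array, palindrome), a
    resampling read-coverage test for uncollapsed haplotigs, and
    Bayesian inference of branch-wise gene duplication and loss rates
    with WGD retention rates under a phylogenetic birth-death model of
    gene-family counts. A synthetic genome-evolution generator provides
    ground-truth test beds for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    seqinr,
    igraph,
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
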