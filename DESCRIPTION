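Package: pilarch
Title: Comparative Architecture Analysis of Type IVa Pilus Gene Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies type IVa pilus (T4aP) gene families in annotated
    bacterial genomes by thresholded local alignment against a reference panel
    with competitive exclusion of type II secretion system paralogs, detects
    genomic gene clusters and classifies their architecture (large main locus
    versus dispersed pilMNOPQ-only organization), analyses flanking-gene
    synteny including the riboflavin kinase (ribF) anchor downstream of pilB,
    computes major-pilin (PilA) sequence diagnostics (prepilin cleavage site,
    N-terminal conservation, disulfide-bonded-loop cysteine pairs, paralog
    similarity), and builds distance-based phylogenies with bootstrap support
    to test monophyly of cluster-resident homologs. Ships a synthetic
    annotated-genome simulator that plants known architectures so every stage
    can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
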