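Package: subkit
Title: Subgenome Phasing and Fractionation Analysis for Paleo-Allopolyploid
    Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-assembly analysis of paleo-allopolyploid plant genomes:
    partitioning scaffolds into parental subgenomes with diagnostic k-mers
    and hierarchical clustering, detecting homoeologous exchange with a
    two-state hidden Markov model over windowed k-mer majorities, clustering
    LTR retrotransposons into subfamilies by Markov clustering and dating
    insertions with the Jukes-Cantor k/2r clock, quantifying biased
    fractionation with exact tests and GO term over-representation, and
    comparing transposable-element densities flanking genes. Includes a
    synthetic allotetraploid genome simulator with full ground truth so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    rtracklayer,
    S4Vectors,
    GenomicRanges,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ape,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
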