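Package: lncage
Title: Discovery and Characterization of Age-Related Long Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering and characterizing age-related long
    noncoding RNAs (AR-lncRNAs) from a leaf-aging expression time course:
    lncRNA identification (class codes, length, abundance and coding-potential
    filters), genomic-location and functional classification (ribosome release
    score, small-RNA precursor detection), negative-binomial differential
    expression over developmental windows, k-means temporal clustering,
    neighbor co-expression analysis, ceRNA (lncRNA-miRNA-mRNA) network
    inference via the hypergeometric test, and a seed-and-extension RNA-RNA
    duplex screen. Includes a fully labelled synthetic-study generator with
    planted ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
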