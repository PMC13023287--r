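Package: triplexscreen
Title: In Silico Screening of Cis-Acting lncRNA:DNA Triplex Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end screen for cis-acting long non-coding RNAs (lncRNAs)
    that may regulate candidate genes through DNA:RNA triplex formation. Pairs
    target genes with lncRNA loci inside +/-50 kb cis windows, scans lncRNA
    transcripts against promoter duplexes for Hoogsteen/reverse-Hoogsteen
    triplex-forming matches, scores the densest binding-site cluster (TFO1)
    against shuffled-sequence and unrelated-promoter controls, intersects
    predicted target sites with CpG islands, filters triplex-forming
    oligonucleotides by secondary-structure accessibility (windowed McCaskill
    partition function, RNAplfold-style unpaired probabilities), and ranks
    gene-lncRNA pairs with a hierarchical filtering strategy. Ships a
    ground-truth synthetic locus generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
VignetteBuilder: knitr
Config/testthat/edition: 3
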