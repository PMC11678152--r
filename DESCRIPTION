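Package: srnaigr
Title: Discovery and Expression Profiling of Intergenic Small RNAs in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering trans-encoded small regulatory RNAs
    (sRNAs) in intergenic regions (IGRs) of GC-rich bacterial genomes such as
    Streptomyces. Extracts and classifies IGRs from genome annotations, calls
    cross-strain conservation by reciprocal-best-hit homology search, screens
    conserved IGR alignments for thermodynamically stable and conserved RNA
    secondary structure with a permutation-based specificity estimate, filters
    putative sRNAs by expression breadth and depth, tests differential
    expression over a growth curve with a minimal negative-binomial Wald
    engine, and calls sRNA-mRNA targets by hybridization energy with
    opposite-expression corroboration. Ships a fully deterministic synthetic
    data generator (diverged strain families with planted structured sRNAs,
    count matrices with planted differential expression and anti-correlated
    targets) together with ground-truth recovery evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
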