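Package: migseqr
Title: In-Silico MIG-seq: ISSR Primer Design, Amplicon Prediction, Read
    Simulation, Stack-Based SNP Genotyping and Locus QC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end in-silico toolkit for MIG-seq (multiplexed
    ISSR genotyping by sequencing), a PCR-based reduced-representation
    sequencing method. Implements combinatorial design of tailed ISSR
    primer sets with multiplex-compatibility screening, prediction of
    amplifiable inter-SSR loci on arbitrary genomes, simulation of the
    MIG-seq library and read structure with PCR- and sequencing-error
    models, demultiplexing and quality preprocessing, a simplified
    stack-based de novo SNP genotyper, locus-level artifact filters
    (singleton variants, replicate discordance, shifted-priming
    pseudo-loci, duplicated loci, paired-end loci), and downstream
    genetic analyses (Mendelian segregation tests in haploid panels,
    clone identification from pairwise SNP mismatches, and population
    differentiation summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
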