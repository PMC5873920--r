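Package: sweepscan
Title: Selection Scans on Phased Haplotypes with Coalescent Neutral Nulls
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects signatures of recent hard and soft selective sweeps in
    phased SNP data. Computes nucleotide diversity, Tajima's D, weighted and
    mean Weir-Cockerham FST, unstandardized nSL, and the pooled haplotype
    homozygosity statistic H12 directly from haplotype matrices read from
    phased VCF files. Significance is assessed by empirical p-values against
    null distributions simulated under a three-population out-of-Africa
    demographic model using a built-in Hudson-style coalescent with
    recombination, and functional gene categories are compared with exact
    two-sided Mann-Whitney U tests with Bonferroni adjustment. Includes a
    synthetic-study generator that plants hard and soft sweeps into neutral
    simulations so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    jsonlite,
    withr,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Rsamtools,
    VariantAnnotation
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
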