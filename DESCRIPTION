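Package: crossqtl
Title: Cross-Species Candidate Gene Prioritization from Mouse QTL and
    Human GWAS Summary Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate genes for complex traits by combining
    quantitative trait locus (QTL) mapping in recombinant inbred mouse
    panels with gene-based association tests on human GWAS summary
    statistics. Implements single-marker likelihood-ratio scans on strain
    means with permutation-based genome-wide thresholds, extraction and
    merging of significant QTL intervals, the GATES (extended Simes) and
    HYST (scaled chi-square hybrid) gene-based tests using pairwise
    linkage disequilibrium, homology-restricted region-specific
    Bonferroni candidate calling, and a guilt-by-association coexpression
    stage (Pearson correlation matrices with probe-count-adjusted
    thresholds, conditional coexpression values, over-representation
    analysis, and first-principal-component synthetic traits). A
    synthetic-data module generates recombinant inbred genotype mosaics,
    strain-mean phenotypes with planted QTL, LD-structured GWAS summary
    statistics, homology maps and modular expression matrices so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
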