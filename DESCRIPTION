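Package: oatmap
Title: Mapping-by-Sequencing Analysis of Pooled F2 Mutant Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for localizing recessive causal mutations in EMS-mutagenized
    crop lines by mapping-by-sequencing. Implements pooled-F2 mutant allele
    frequency computation with a sliding-window median scan, SNP functional
    effect annotation against gene models, background variant subtraction,
    a multi-stage candidate gene filtering funnel combining variant impact,
    genomic location, read support and tissue expression, an orthogroup-based
    candidate screen, and the associated segregation and rank-based phenotype
    statistics. Includes a meiosis-level simulator of an F2 bulked segregant
    experiment (crossovers, phenotype selection, pooled short-read sampling)
    for validating the analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
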