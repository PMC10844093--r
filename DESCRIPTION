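Package: accessGRN
Title: Gene Regulatory Network Inference from Chromatin Accessibility in AML
Version: 0.1.0
Authors@R: person("The", "accessGRN authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for regulatory genomics of acute myeloid
    leukemia subtypes from DNaseI-seq style data. Covers normalization and
    correlation clustering of tag counts at distal hypersensitive sites,
    fold-change ranking and group-specific site calling, digital genomic
    footprinting via a binomial cleavage-depletion statistic, position weight
    matrix scanning and condition-specific motif enrichment, enhancer-to-gene
    assignment from promoter-capture interaction maps with a nearest-TSS
    fallback, construction of a transcription factor gene regulatory network,
    fold-change differential expression with hypergeometric overlap tests, and
    the LSC17 leukemia stemness score. Ships a seeded synthetic-study
    generator with a known planted regulatory program so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
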