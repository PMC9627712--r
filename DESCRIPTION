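Package: rohload
Title: Runs of Homozygosity, Inbreeding and Mutation Load in Small Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies inbreeding and mutation load from multi-sample SNP
    genotypes, as used in conservation genomics of severely bottlenecked
    populations such as desert pupfishes. Detects runs of homozygosity (ROH)
    per individual with a two-state hidden Markov model decoded by the Viterbi
    algorithm, and summarises them as F_ROH inbreeding coefficients,
    length-class genome fractions and tract ages in generations. Classifies
    coding SNPs as synonymous, missense or stop-gained against a reference
    genome and annotation, polarizes genotypes into ancestral/derived classes,
    and computes genotype-class mutation-load profiles with ANOVA/Tukey group
    comparisons, filtered loss-of-function allele-frequency tables, and exact
    binomial tests for enrichment of loss-of-function variants inside ROHs.
    Also provides group-private fixed-variant and deletion filters,
    Weir-Cockerham F_st, and harmonic-mean effective population size from
    census counts. Ships a seeded synthetic-cohort simulator with truth tables
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
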