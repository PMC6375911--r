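Package: petrelpop
Title: Population Structure and Two-Island Demographic History from
    mtDNA Haplotypes and RAD-Seq SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the population structure and recent
    demographic history of a fragmented island seabird system. Implements
    hierarchical analysis of molecular variance (AMOVA) with
    Phi-statistics and permutation tests, mtDNA haplotype summary
    statistics (haplotype diversity, nucleotide diversity, Tajima's D),
    Benjamini-Yekutieli corrected pairwise Phi-ST matrices, windowed
    Weir-Cockerham Fst, folded joint (2D) minor-allele site frequency
    spectra with hypergeometric projection and locus block bootstrap, a
    structured-coalescent simulator for two-deme isolation-with-migration
    models with migration-regime and size changes, composite-likelihood
    demographic model fitting with AIC comparison, and the mutation-rate
    calibration arithmetic used to scale mutation-scaled estimates to
    effective sizes and migrant numbers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vcfR,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
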