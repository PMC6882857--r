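Package: haplophaser
Title: Statistical Haplotype Phasing with PBWT Selection and a Diploid
    Li-Stephens MCMC
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates haplotypes from unphased diploid genotypes using a
    positional Burrows-Wheeler transform (PBWT) to select conditioning
    haplotypes, a diploid Li-Stephens hidden Markov model evaluated on
    compact genotype graphs, and an MCMC scheme with burn-in, pruning and
    main iterations. Supports reference panels of phased haplotypes,
    haplotype scaffolds of pre-phased genotypes, sequencing-read phase
    sets (VCF PS field) as probabilistic constraints, and IBD2 protection
    between duplicated or sibling samples. Includes a mosaic population
    simulator with trio truth and switch-error-rate evaluation metrics,
    plus VCF and genetic-map input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    optparse,
    VariantAnnotation,
    Rsamtools,
    SummarizedExperiment,
    GenomicRanges,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
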