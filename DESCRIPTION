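Package: ygeneflow
Title: Simulation and Detection of Y Chromosome Introgression Between
    Divergent Primate Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study interspecific Y chromosome introgression with
    population-genomic simulation and summary statistics. Implements a
    structured-coalescent simulator with instantaneous introgression pulses
    over a configurable demographic model, an infinite-sites mutation
    overlay, Patterson's D with block-jackknife Z-scores, windowed f_d and
    pixy-style dXY with coalescence-time scaling, a forward Wright-Fisher
    simulator of Y-linked allele fixation under haploid selection with a
    Kimura diffusion oracle, a two-locus Y-pseudoautosomal linkage model,
    coverage-based pseudoautosomal-region and copy-number scans,
    sliding-window neighbor-joining topology classification, a screen for
    fixed amino-acid differences in Y-linked genes, and synthetic-data
    generators that emulate the study design of a guenon Y introgression
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    ape,
    Biostrings,
    vcfR,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
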