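Package: capemine
Title: Discovery and Targeted Quantification of CAP-Derived Peptides
Version: 0.1.0
Authors@R:
    person("capemine", "developers", email = "capemine@example.org",
           role = c("aut", "cre"))
Description: Mines proteomes for CAP-superfamily precursors of C-terminally
    encoded CAPE peptides (the conserved CNYx|PxGNxxxxxPY cleavage
    architecture), computes peptide masses and b/y fragment ladders, designs
    targeted LC-MS/MS transition assays with sequence-substituted internal
    standards, quantifies the endogenous peptide label-free from transition
    chromatograms with internal-standard normalization, screens expression
    matrices for salt-specific regulation, and summarizes semi-quantitative
    seedling phenotypes. Ships a seeded synthetic-data generator (planted-motif
    proteomes, Gaussian transition peaks, expression matrices with planted
    fold changes) so every pipeline stage can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
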