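Package: scdblcall
Title: Doublet Detection for Single-Cell DNA Sequencing Read Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Standalone maximum-likelihood doublet detection for
    medium-to-high coverage single-cell DNA sequencing (scDNA-seq) data.
    Models the characteristic variant allele frequency (VAF) spectrum of
    droplets containing two cells, accounting for allelic dropout during
    whole-genome amplification, amplification copy errors and allelic
    imbalance via a beta-binomial read-count likelihood. Provides a
    closed-form per-droplet classifier, data-driven estimation of the
    genotype priors and error parameters, a truth-labelled droplet
    simulator with clonal genotypes, single-nucleotide variants and
    copy-number aberrations, and benchmark metrics (precision, recall,
    F1 overall and per doublet type).
License: BSD_3_clause + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
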