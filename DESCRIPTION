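Package: mlgenocall
Title: Maximum-Likelihood Genotype Calling from Nucleotide Read Quartets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood genotype calling for population
    high-throughput sequencing data summarised as per-individual
    nucleotide read quartets (counts of A, C, G and T at a site).
    Provides a population-level genotype-frequency and error-rate
    estimator with a likelihood-ratio polymorphism test, a Bayesian
    genotype caller for low-coverage diploid data that uses the
    estimated frequencies as empirical priors, a prior-free
    high-coverage caller supporting arbitrary numbers of alleles,
    triploid and tetraploid extensions, a read-quartet simulator with
    recorded truth, and scoring utilities for correct-call rates,
    allele-frequency bias and polymorphism-detection power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
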