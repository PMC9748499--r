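Package: mobileBF
Title: Exact Bayes Factors for Detecting Graft-Mobile Transcripts from
    RNA-Seq Read Counts
Version: 0.1.0
Authors@R:
    person("mobileBF", "Developers", email = "mobilebf@example.org",
           role = c("aut", "cre"))
Description: Decides whether transcripts observed in grafted plant tissue
    originated from the distal genotype (graft-mobile messenger RNA) or are
    explainable by sequencing and mapping errors. Error rates per single
    nucleotide polymorphism (SNP) are inferred from homograft reference data
    under a conjugate Beta-binomial model, and per-SNP log10 Bayes factors
    comparing an errors-only hypothesis against a two-genotype hypothesis are
    computed exactly in log space and summed over SNPs and replicates.
    Includes a binomial read-count simulator with known labels, a blending
    generator that titrates one homograft count table into another, absolute
    read-count threshold baseline classifiers, confusion-matrix evaluation,
    benchmark sweeps over read depth and SNP number, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
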