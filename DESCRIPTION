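Package: poolacc
Title: Accuracy Assessment of Pooled-Sequencing Allele Frequency Estimation
Version: 0.1.0
Authors@R: person("Pool-seq", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates pooled whole-genome re-sequencing of panels of
    isogenic strains (unequal per-strain DNA contribution, variable read
    depth, optional per-read sequencing error) and quantifies how well
    pooled read fractions recover population allele frequencies. Provides
    Lin's concordance correlation and squared relative error under a
    frequency-binned resampling design, binomial-expectation simulations
    for best-case accuracy at observed depths, estimation of per-strain
    DNA contributions from private SNPs, a transparent binomial-threshold
    SNP caller with false positive and false negative rates by folded
    frequency bin, and a command-line interface for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
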