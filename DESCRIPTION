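Package: relkit
Title: Pedigree and Genomic Relationship Estimation with MAF-Restriction Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates additive genetic relationships from pedigree records and
    genomic relationships from biallelic genotype data under minor-allele-frequency
    restriction scenarios, using an allele-frequency-weighted (Yang) estimator and
    an allele-sharing (similarity) estimator. Includes an exact test for departure
    from Hardy-Weinberg proportions, pedigree inbreeding and pedigree-depth tools,
    statistical comparison of relationship and inbreeding estimates across data
    sources and scenarios, and a gene-dropping simulator with tracked
    identity-by-descent ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
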