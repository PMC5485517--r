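Package: episcreen
Title: Two-Stage Detection of High-Order SNP Interactions in Case-Control Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects K-locus (K >= 3) interactions among single-nucleotide
    polymorphisms (SNPs) in case-control genotype data with a two-stage
    strategy: a screening stage that tests all SNP pairs by a chi-squared
    association test with an "intermediate + significant" retention band and
    removes pairs whose association is driven by strong marginal effects via
    a logistic-regression likelihood-ratio test, and a search stage that
    finds K-locus interactions by exhaustive enumeration over the merged
    candidate SNP set or, for large candidate sets, by ant colony
    optimization. Contingency tables are built with a bitwise genotype
    encoding and popcount counting. A companion simulator generates
    case-control data under parameterized penetrance models (multiplicative,
    threshold and pure-epistasis three-locus families, or arbitrary
    user-supplied penetrance tables) and estimates detection power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
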