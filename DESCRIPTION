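Package: dipalign
Title: Recombination-Aware Alignment Distances Between Diploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distances between phased diploid genomes represented as
    pair-wise alignments of their two haplotypes, allowing free (or
    penalized) recombination of the haplotypes. Implements the cubic-time
    pair-of-haploids-to-diploid distance, the synchronized
    diploid-to-diploid distance in quadratic time and in a banded
    threshold-doubling variant, exhaustive brute-force references for
    small instances, classic weighted edit distance with traceback, and a
    diploid-pair simulator with planted variants, block recombination and
    independent per-strand mutations. Intended for variant-calling and
    phasing evaluation, where switch errors between the two haplotypes
    should not be charged as sequence differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
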