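Package: xibdne
Title: X-Chromosome Effective Population Size from Identity-by-Descent Segments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the recent X-chromosome effective population size from
    identity-by-descent (IBD) segments and combines it with an autosomal
    estimate to recover female- and male-specific effective population sizes
    over the past hundred generations, with paired-bootstrap confidence
    intervals. Includes the coalescent length model for X-linked IBD segments,
    the preprocessing adjustments needed to analyse X-chromosome IBD data
    (haploid-male deduplication, sex balancing, close-relative removal with
    haplotype-pair accounting, equal-cM chromosome splitting), a simplified
    nonparametric spectrum-matching Ne estimator, and a two-sex Wright-Fisher
    simulation engine used to validate the theory and generate synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
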