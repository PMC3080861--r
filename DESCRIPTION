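Package: admixdate
Title: Dating and Testing Population Admixture with f-Statistics and
    Admixture LD Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Formal tests for population mixture (the 4 Population and 3
    Population tests with block-jackknife Z-scores), f4-ratio estimation of
    ancestry proportions, and dating of admixture events from the exponential
    decay of admixture linkage disequilibrium with genetic distance
    (weighted pairwise LD scores binned by distance and fitted by least
    squares). Includes a haplotype-mosaic simulator of admixed genomes
    (single-pulse, double-pulse and continuous gene flow) built on a
    Balding-Nichols allele-frequency model, simulation-based bias correction
    of date estimates, EIGENSTRAT genotype input/output, genetic-map
    interpolation, and inverse-variance averaging of dates across
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
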