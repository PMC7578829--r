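Package: broodmate
Title: Mate Allocation for Conservation Broodstock from Multilocus Genotypes
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the genetic diversity of progeny for every possible
    male-female mating in a captive broodstock genotyped at codominant loci
    (e.g. microsatellites), ranks candidate pairs with a weighted composite
    index combining expected progeny heterozygosity, expected allele number
    and the share of weak heterozygous genotypes, selects disjoint sets of
    breeding pairs for controlled mating, and searches male/female subsets
    for group spawning that maximize the number of alleles transmitted to
    the progeny. Includes per-locus diversity statistics (observed and
    expected heterozygosity, allele counts), a synthetic genotype-panel
    simulator for testing and power studies, delimited-table and Genepop
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    igraph,
    yaml,
    tools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
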