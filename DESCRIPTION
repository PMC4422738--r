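Package: founderest
Title: Minimum Founder Number Estimation from Microsatellite Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the minimum number of founder individuals whose
    genotypes suffice to carry all microsatellite alleles observed in a
    genetic cluster of an introduced population. Implements three
    genotype-resampling models (allele resampling without replacement,
    resampling from empirical allele frequencies, and equal allele
    frequencies), a Monte Carlo capture-probability decision rule with an
    exact inclusion-exclusion oracle, and low-frequency-allele filtering
    to guard against recent immigrants. Also provides descriptive
    population-genetic statistics per cluster (allelic richness by
    rarefaction, observed and unbiased expected heterozygosity, private
    alleles, pairwise Weir-Cockerham F_ST), readers and writers for
    GENEPOP and long-form genotype tables, and a Wright-Fisher
    founder-event simulator for generating realistic synthetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
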