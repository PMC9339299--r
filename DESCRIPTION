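Package: tetradkit
Title: Tetrad Analysis for Yeast Meiosis: Map Distances, Interference,
    Gene Conversion, and a Forward Meiosis Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the classical analysis of dissected Saccharomyces
    cerevisiae tetrads: segregation scoring of heterozygous markers,
    parental-ditype/tetratype/nonparental-ditype classification of genetic
    intervals, Perkins map distances with multinomial delta-method standard
    errors, Papazian expected nonparental-ditype counts and crossover
    interference ratios, gene-conversion tabulation with the associated
    two-proportion and exact tests, spore-viability summaries and
    meiosis-I nondisjunction inference from mating phenotypes, and a
    forward simulator of single meioses (counting-model chiasma
    interference, gene conversion, missegregation, spore death) for
    validating every estimator by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
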