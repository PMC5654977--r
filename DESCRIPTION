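Package: clonedrift
Title: Clonal Dynamics of Mutant Stem Cells in Epithelial Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the competition of somatic mutant clones in
    two-dimensional stem-cell compartments such as the basal layer of human
    epidermis. Provides a stochastic simulator of clonal dynamics on a
    hexagonal lattice (neutral drift, advantaged mutants, migration, and a
    heterogeneous stem/transit-amplifying compartment with energy-gated
    migration), closed-form clone-size distribution models (neutral drift,
    boundary nucleation, exponential growth) with incomplete-moment and
    power-law fitting, a strand-aware beta-binomial likelihood-ratio caller
    for subclonal variants in deep targeted sequencing, and synthetic-data
    generators for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    GenomicRanges,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
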