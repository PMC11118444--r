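Package: popgst
Title: Identity-by-State Hierarchies and G-Statistics for Structured
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Diversity-based analogs of Wright's hierarchical F-statistics
    built from probabilities of identity by state (IBS).  Provides exact
    one-generation identity recursions and steady states for the island
    model with partial self-fertilization and K-allele mutation, a
    structured-coalescent pair-identity solver for an asymmetric two-deme
    model (including the conditions under which deme-specific FST analogs
    go negative), estimators of the IBS hierarchy from genotype tables or
    VCF, recursive pedigree inbreeding coefficients, and forward and
    backward stochastic simulators that serve as independent verification
    oracles for the analytic results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
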