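Package: mutualev
Title: Agent-Based Evolution and Expression-Constrained Flux Analysis of
    Obligate Cross-Feeding Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying serial-transfer co-evolution of an obligate
    mutualistic yeast-bacterium community selected for costly vitamin
    secretion. Provides a spatial agent-based model of cross-feeding on a
    toroidal patch grid with serial-transfer dilution, a replicate-sweep
    driver for mutant-invasion experiments across mixing strengths and
    secretion levels, a relative-expression-constrained flux-balance fit
    that predicts flux redistribution from proteomic fold-changes, the
    phenotype-quantification formulas used in such studies (growth rates
    from log2-OD slopes, generation counts, screening fold-changes,
    aggregation and biofilm readouts), and seeded synthetic-data
    generators so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    boot,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
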