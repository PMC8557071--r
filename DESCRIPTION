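Package: cellforest
Title: Lineage-Forest Analytics for Bacterial Single-Cell Movies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing cell-tracking output of bacterial time-lapse
    ("single-cell movie") experiments. Tracked cells are organised into a forest
    of lineage trees (one node per cell instance per frame) and a forest of
    division trees (one node per cell lifespan), with constraint-based
    subpopulation selection, per-cell exponential/linear growth-model fitting,
    Baranyi-Roberts colony growth curves, maximum-likelihood characterisation of
    single-cell stochasticity with BIC model selection, kin-pair (sibling,
    cousin, mother-daughter) correlation analysis, detection and surgical
    correction of cell-tracking errors, and a seeded stochastic micro-colony
    simulator that emulates generation-indexed growth-parameter variability for
    end-to-end testing without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    data.table,
    igraph,
    minpack.lm,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
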