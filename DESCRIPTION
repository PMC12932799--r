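Package: richgap
Title: Lower-Bound Species Richness Estimation and Taxonomic Gap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates lower bounds of species richness for large occurrence
    datasets and quantifies the taxonomic gap (estimated minus described
    species). Provides a six-rule occurrence-record cleaning filter with
    Darwin Core style inputs, abundance-assemblage construction augmented by
    a fitted power-law literature curve for checklist species lacking any
    occurrence records, nonparametric richness estimators (Chao1, iChao1,
    and rarefaction-extrapolation of Hill number q = 0) with log-transformed
    and bootstrap confidence intervals, an iterative resampling engine with
    region exclusion rules and gap reporting, orthographic-variant
    deduplication of synonym lists, species-accumulation curves, and a
    synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    igraph,
    jsonlite,
    minpack.lm,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
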