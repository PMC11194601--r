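Package: holcdiv
Title: Biodiversity Disparities Across Historical HOLC Neighborhood Grades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking historical Home Owners' Loan
    Corporation ("redlining") neighborhood grades to urban wildlife
    biodiversity from contributory (iNaturalist-style) observation records.
    Provides a synthetic-data generator with known ground truth (HOLC-like
    polygons, impervious-surface grids, and observation records), ingest and
    filtering of occurrence data with a point-in-polygon spatial join,
    species-accumulation curves with an analytic rarefaction oracle, a
    hierarchical Bayesian Poisson model of neighborhood species richness with
    city-level random intercepts and grade slopes and an area-by-effort
    log-offset, and PERMANOVA on Jaccard dissimilarities with
    Benjamini-Hochberg-adjusted pairwise grade comparisons.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    purrr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
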