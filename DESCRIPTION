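Package: quadlead
Title: Virtual Quadripolar Lead Design Trials for Cardiac
    Resynchronization Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico trial platform for multipoint-pacing lead design
    in cardiac resynchronization therapy. Generates idealized biventricular
    tetrahedral anatomies with controlled heart-failure versus
    reverse-remodelled morphological variability, computes universal
    ventricular coordinate fields and 17-segment AHA maps, solves an
    anisotropic eikonal model of ventricular activation with a fast
    endocardial conduction layer and thickness-based scar, places virtual
    quadripolar leads along idealized epicardial vein tracks, scores
    electrical synchrony (total activation time and the time to activate
    90 percent of the myocardial volume) against a right-ventricular pacing
    baseline, and runs cohort-level optimal-lead-design selection by exact
    minimal set cover, Ward hierarchical clustering of response matrices,
    nonparametric statistics, and one-at-a-time sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
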