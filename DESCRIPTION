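Package: biofilmflow
Title: Quantifying Biofilm Growth and Dispersal in a Hyperbolic Flow Cell
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of confocal time-lapse imaging of bacterial biofilms
    grown in a hyperbolic flow cell that imposes a linearly decreasing
    centerline velocity. Provides design and depth-averaged (Hele-Shaw)
    verification of the channel geometry, a ground-truthed synthetic
    confocal time-lapse generator (clonal exponential growth, single-cell
    shedding, downstream-first dispersal, PSF blur and shot noise), 3-D
    threshold/connected-component segmentation with a minimum object size,
    per-window biovolume metrics and normalisation, exponential growth-rate
    and doubling-time fitting, dispersal-onset detection, spatial
    propagation statistics and between-run reproducibility tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
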