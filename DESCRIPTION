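Package: rvimap
Title: Re-Entry Vulnerability Index Mapping on an Idealized Infarct Test-Bed
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and characterization of re-entry vulnerability index
    (RVI) maps from activation and repolarization times recorded on arbitrary
    electrode sets. Implements the pairwise activation-repolarization interval,
    three global interpolation schemes (nearest-neighbour, average, minimum)
    with a configurable search radius, and vulnerable-region quantification.
    Ships an in-silico test-bed: an idealized two-dimensional infarct sheet
    (scar, border zone, conducting isthmus), a monodomain reaction-diffusion
    simulator with a two-variable phenomenological ionic model and S1-S2
    pacing, activation/repolarization marker extraction, clinically realistic
    sparse recording grids (decapolar, fan, multipolar random clusters), noise
    injection, and closed-form synthetic marker fields for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
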