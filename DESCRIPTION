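Package: bupop
Title: Bottom-Up Population Estimation from Microcensus Density Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Census-independent ("bottom-up") population estimation for
    settings where national census data are outdated or unavailable.
    Fits type-specific log-normal population-density models to microcensus
    enumeration-zone observations, produces gridded population estimates
    over a binary settlement raster, and derives Monte Carlo prediction
    intervals for arbitrary regions of interest via convolution of
    reference-scale density draws. Includes subpopulation (under-5)
    estimation against coarse demographic fraction grids, two-epoch
    settlement-change metrics, and a synthetic-landscape generator that
    emulates sparse settlement mosaics, residential-type block layers and
    two microcensus sampling designs so the whole pipeline is testable
    without proprietary imagery or survey data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
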