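Package: moveshift
Title: Compositional Analysis of 24-Hour Movement Behaviours and Lung Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for compositional data analysis of
    24-hour movement behaviours (sleep, sedentary time, light and
    moderate-to-vigorous physical activity) against a continuous clinical
    outcome such as percent-predicted FEV1. Provides Aitchison-geometry
    primitives (closure, pivot isometric log-ratio coordinates and their
    inverse, compositional means, variation matrices), ordinary
    least-squares regression on ilr coordinates with the full set of pivot
    rotations, isotemporal-substitution (time-reallocation) predictions
    with confidence intervals on whole grids and within strata, a
    logistic-normal synthetic cohort generator with known ground truth,
    ternary prediction surfaces, and a one-call reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    patchwork,
    broom,
    withr,
    yaml
Config/testthat/edition: 3
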