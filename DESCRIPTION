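Package: omegarich
Title: Bias-Corrected Asymptotic Species Richness Estimation from
    Spatial Abundance Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates asymptotic species richness from spatially
    partitioned abundance surveys using a mechanistic observation
    probability model. A species' chance of being recorded at least once
    depends on its observable abundance per patch, its patch occupancy
    and the number of patches sampled; dividing observed richness by the
    mean estimated observation probability across observed species gives
    the bias-corrected omega family of estimators (exact, second-order
    Taylor, and mean-field variants). Also provides the classic
    comparison estimators (Chao1, Chao2, ACE, jackknifes), a
    dependence-aware block bootstrap for precision, a community
    simulator with lognormal abundances and patch occupancy, a
    six-measure benchmarking harness, and spatial subsampling /
    local downsampling experiments for multi-year datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
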