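Package: flyAL
Title: Connectome-Parameterized Antennal-Lobe Simulation and Individuality Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Leaky-integrate-and-fire simulation of the Drosophila antennal lobe
    parameterized by connectome synapse counts, with generators of idiosyncratic
    circuits (cell-type bootstrapping and glomerular synapse-density resampling),
    population-level PCA and decoding analyses of glomerulus-odor response
    matrices, and simulation-based inference of the latent calcium-behavior
    correlation corrected for measurement repeatability. Ships synthetic-data
    generators emulating the structure of connectome rosters, odorant-response
    matrices and paired calcium/behavior datasets so every stage runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    jsonlite,
    yaml,
    generics,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
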