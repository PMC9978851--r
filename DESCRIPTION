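Package: phenofrass
Title: Annual Forest Defoliation from Frass Deposition and Larval Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates annual insect defoliation (frass deposition and total
    foliage biomass loss, kg/ha) for spring-feeding forest Lepidoptera such as
    the jack pine budworm (Choristoneura pinus) and the spongy moth (Lymantria
    dispar dispar). Links daily simulated larval-instar population proportions
    to interval-censored frass-trap field data in two steps: simplex-constrained
    optimization of per-instar feeding weights against observed deposition
    rates, and imputation of unsampled periods of the feeding season via the
    cumulative density function of the weighted-larvae signal. Includes
    leave-one-plot-out and leave-one-interval-out cross-validation, a
    synthetic-data generator emulating the assumed data structure, tidy() and
    glance() methods, ggplot2 diagnostics, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
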