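Package: rosecanopy
Title: Functional-Structural Simulation of Light and Photosynthesis in
    Cut-Rose Canopies with Bent Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional cut-rose (Rosa hybrida) canopies with
    upright flower shoots and bent-shoot leaf clouds, traces diffuse sky light
    through the canopy with a Monte Carlo ray tracer, computes per-leaf net
    photosynthesis from non-rectangular-hyperbola light responses with a
    light-gradient distribution of photosynthetic capacity, reconstructs
    greenhouse light from outside global radiation and lamp/screen control
    rules, integrates daily and cumulative carbon budgets by shoot class over a
    growth cycle, and runs the assimilate-translocation accounting that
    attributes upright-shoot biomass gain to bent-shoot photosynthesis.
    Includes synthetic-data generators for plant architecture, leaf
    light-response curves and weather so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
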