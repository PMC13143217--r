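Package: grousevision
Title: Visual-System Modelling for Bird Collision-Risk Assessment
Version: 0.1.0
Authors@R:
    person("Avery", "Moreau", email = "avery.moreau@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising an avian visual system from desk-scale
    measurements and for turning those characteristics into collision-mitigation
    guidance, developed around the black grouse (Lyrurus tetrix). Implements
    Govardovskii A1 visual-pigment templates with non-linear lambda-max fitting
    and bootstrap confidence intervals, cone oil-droplet filtering and effective
    spectral sensitivities, contrast-sensitivity-function estimation from
    optocollic-reflex trial tables, eye-size-based acuity and detection-distance
    geometry, visual-field arithmetic with correction of perimeter measurements
    to infinity, and Michelson-contrast analysis of marker reflectance spectra.
    A seeded synthetic-data module emulates every input so the full analysis
    runs reproducibly without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
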