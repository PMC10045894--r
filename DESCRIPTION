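Package: spheromech
Title: Viscoelastic Analysis of Spheroid Micropipette Aspiration in Microfluidic Chips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microfluidic micropipette aspiration of
    multicellular spheroids. Extracts creep lengths of aspirated tissue
    tongues from binarized time-lapse image stacks, fits the modified
    Maxwell (spring-dashpot) creep model by bounded nonlinear least
    squares, and converts the fitted parameters into elastic modulus,
    viscosity and relaxation time using an effective-radius correction for
    rectangular aspiration channels, with first-order propagation of fit
    and instrument uncertainties. Includes a synthetic-data generator
    (cohorts of noisy creep curves and rendered multi-channel image stacks
    with artifact modes), a lumped hydraulic-resistance model of the
    pressure redistribution across parallel aspiration pockets, and
    cohort-level summary statistics and significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
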