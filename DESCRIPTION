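Package: poroflow
Title: Poroelastic Modelling of Intracellular Pressure Gradients and Flows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the poroelastic mechanics of the cytoplasm
    at the whole-cell scale. Provides a transient Biot consolidation finite
    element solver on axisymmetric cell geometries, in-silico protocols for
    localised indentation, fluid microinjection and localised
    depressurisation through a low-permeability cortex layer, estimators
    that convert bead displacement traces and pressure-step datasets into
    time lags, relaxation times and hydraulic permeability via Darcy's law,
    two-stage inference of elastic modulus and poroelastic diffusion
    constant by matching forward simulations to observations, closed-form
    pore-size scaling calculators, a defocusing-microscopy ring-tracking
    algorithm for nanometre-scale bead z-displacements, and synthetic data
    generators so that every stage of the analysis is testable without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
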