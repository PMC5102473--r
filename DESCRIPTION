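Package: allomax
Title: Allometry of Maximum Somatic Growth Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reanalysing the allometric scaling of maximum somatic
    growth rate with body mass. Implements a dimensionless framework for the
    three standard sigmoidal growth models (logistic, Gompertz, von
    Bertalanffy) with constrained least-squares curve fitting; weighted
    log-log ordinary least squares with shear-transformation diagnostics,
    confidence and single-prediction bands, and fixed-slope mass-adjusted
    rates; species-level overlap classification via convex hulls, residual
    parallelograms and nearest-regression-line assignment; polynomial
    curvature analysis ranked by small-sample corrected AIC; tests of the
    proposed growth-metabolism link including the ontogenetic BMR adjustment
    and correlation-transitivity analysis; bootstrap demonstrations of the
    ecological fallacy; and seed-deterministic synthetic-data generators that
    emulate the statistical structure of published growth-rate and metabolic
    compilations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
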