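Package: dynogram
Title: Dynamic and Static Nomograms for Regression and Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained engine for turning regression models into
    nomograms, static and dynamic. Fits linear models, generalised linear
    models (logistic, Poisson, gamma) by iteratively reweighted least squares,
    and Cox proportional hazards models by Newton-Raphson on the partial
    likelihood with a Breslow baseline hazard; supports factors, restricted
    cubic splines and interactions in the design matrix. Computes
    response-scale predictions with confidence intervals via the inverse link,
    survival curves with at-risk-based alpha blending, static nomogram
    geometry (point rulers, total-points and response axes) rendered to SVG
    and JSON, and an interactive scenario session that exports self-contained
    deployable prediction bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    carData,
    xml2,
    optparse
Config/testthat/edition: 3
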