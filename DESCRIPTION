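Package: gwwr
Title: Geographically Weighted Weibull Regression for Right-Censored Spatial Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits parametric Weibull regression models to right-censored,
    nonnegative continuous responses whose covariate effects vary over space.
    Provides the global censored Weibull regression model with analytic
    gradient and Hessian, damped Newton-Raphson maximum likelihood, and the
    geographically weighted extension in which coefficients are estimated at
    every observation site by kernel-weighted local likelihood with per-site
    adaptive bandwidths selected by BIC. Includes Wilks and Wald inference for
    the global model, similarity, simultaneous and per-site partial tests for
    the local model, exact finite-sample Kolmogorov-Smirnov goodness-of-fit
    critical values, multicollinearity (VIF) and Glejser spatial-heterogeneity
    screening, backward covariate elimination, goodness-of-fit summaries
    (BIC, GCV, McFadden R-squared, MAPE), effect-ratio interpretation measures
    on the survival, distribution, hazard and mean scales, and a seeded
    generator of spatially varying censored Weibull datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr
Suggests:
    optparse,
    geosphere,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
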