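Package: fovpower
Title: Model Selection and Power Analysis for Field-of-View Immunostaining Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed-effects modelling of clustered immunohistochemistry cell
    counts scored over microscope fields-of-view (FoV), as used for Ki67
    positivity in patient-derived explant studies. Provides six candidate
    error distributions for overdispersed counts (binomial, beta-binomial,
    Poisson, generalized Poisson, and negative binomial with linear or
    quadratic mean-variance), a Laplace-approximated maximum-likelihood
    fitter for models with treatment and batch fixed effects and random
    intercepts for sample nested within individual, AIC-based comparison of
    the candidate families, a synthetic-data generator emulating the
    patient/sample/FoV hierarchy, and a simulation-based power study over a
    grid of FoV counts and cells counted per FoV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    readr,
    tibble,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    pracma,
    withr
Config/testthat/edition: 3
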