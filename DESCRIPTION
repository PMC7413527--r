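Package: npkresponse
Title: Site-Specific Dose-Response Modelling for Potato Fertilizer Trials
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for site-specific nitrogen, phosphorus and potassium
    fertilizer recommendation in potato cropping systems. Implements
    compositional preprocessing of soil and tuber-size data with isometric
    log-ratio balances, weather indices (cumulative rainfall, Shannon rainfall
    diversity, mean temperature, growing degree-days), a hierarchical
    tri-variate Mitscherlich dose-response surface with a random intercept on
    the asymptote, four machine-learning response models (k-nearest neighbors,
    random forest, single-hidden-layer neural network, Gaussian process with
    Matern kernel) tuned by random-search cross-validation, and economic or
    agronomic optimal N-P-K dose estimation on Monte-Carlo dose grids,
    including Gaussian-process posterior-sampled dose distributions with
    conditional-expectation percentile recommendations. A seeded synthetic
    field-trial generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    digest,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
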