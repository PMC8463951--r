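Package: spatialdosc
Title: Spatial Regression Modelling of Day-of-Surgery Cancellation Rates
    Across Census Tracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small-area analysis of day-of-surgery cancellation
    (DoSC) rates at the census-tract level: empirical Bayes shrinkage of
    crude tract rates toward a beta prior, row-standardised inverse-distance
    contiguity weights, global Moran's I permutation tests and variance
    inflation factor screening, maximum-likelihood spatial regression
    (spatial lag, error, Durbin, Durbin error, moving average and SARAR
    families, with optional L2 penalties), nested cross-validation with
    permutation feature importance, geographically weighted local
    correlation of observed versus predicted rates, and a synthetic
    tract-lattice generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
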