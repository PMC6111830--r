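Package: hyperchla
Title: Hyperspectral Chlorophyll-a Retrieval with ISE-PLS and Band-Ratio Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieval of chlorophyll-a concentration from hyperspectral
    water-leaving reflectance of coastal waters. Implements the ocean
    chlorophyll empirical algorithms (OC2/OC3/OC4, version 6 polynomials)
    with local recalibration, spectrally tuned three-band and NIR/red
    two-band semi-analytical indices, and partial least squares regression
    with iterative stepwise elimination of wavebands (ISE-PLS) driven by
    predictor importance, leave-one-out cross-validation, and a
    jaggedness-penalised choice of the number of latent variables. A
    forward bio-optical simulator generates paired reflectance/chlorophyll
    datasets so every stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
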