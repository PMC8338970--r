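Package: chaostoch
Title: Discriminating Chaotic from Stochastic Time Series with Ordinal
    Patterns and a Neural Correlation-Exponent Regressor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies univariate time series as chaotic or stochastic and
    quantifies their temporal correlations.  A small feed-forward network,
    trained exclusively on flicker (1/f^alpha) noise, regresses the spectral
    exponent alpha from the D! = 720 ordinal-pattern probabilities of the
    series (Bandt-Pompe symbolic analysis with D = 6).  The normalized
    distance Omega between the permutation entropy of the series and the
    permutation entropy of flicker noise at the estimated exponent separates
    stochastic signals (Omega near 0) from chaotic ones (Omega large).
    Includes seeded generators for colored noise, fractional Brownian
    motion/noise, chaotic maps and the Lorenz flow, plus scripted
    reproductions of the validation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
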