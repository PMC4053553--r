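Package: pphmap
Title: Joint Bayesian Disease Mapping of Potentially Preventable
    Hospitalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Small-area analysis of potentially preventable hospitalization
    (PPH) rates: indirect standardization and standardized hospitalization
    ratios, extremal-quotient and empirical-Bayes variation statistics,
    Moran's I with a permutation test, and joint Bayesian mapping of several
    conditions with a Shared Component Model fitted by a Metropolis-within-
    Gibbs sampler written in C++. Includes Besag-York-Mollie and
    non-spatial exchangeable comparators, DIC model comparison, posterior
    variance decomposition into shared and condition-specific spatial
    patterns, exceedance-probability map surfaces, convergence diagnostics,
    and a calibrated synthetic areal-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
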