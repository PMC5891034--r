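Package: rigidsep
Title: Separated-Representation Evaluation of Net Interactions Between
    Rigid Particle Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the net distance-dependent interaction (energy, force,
    moment) between two rigid bodies made of many particles, with per-pose
    cost independent of the particle counts. The pairwise law is surrogated
    as a polynomial in squared distance, expanded under a rigid pose family
    into pose-basis monomials times geometry coefficients, and the geometry
    coefficients are pre-summed over all particle pairs into characteristic
    constants. Includes a brute-force pairwise oracle, error metrics,
    regression-error propagation simulation, and synthetic randomly charged
    box generators for end-to-end experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
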