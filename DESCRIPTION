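Package: foodwebspectra
Title: Evolutionary Assembly of Lotka-Volterra Food Webs and Their
    Community-Matrix Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the evolutionary assembly of food webs by sequential
    invasion under generalised Lotka-Volterra dynamics with a single basic
    nutrient source, covering treelike, trophically coherent (non-omnivorous)
    and omnivorous assembly rules.  Provides analytic steady states, community
    (Jacobian) matrices and their eigenvalue spectra, closed-form two-species
    eigenvalue theory, spectral summaries (purely-real fractions, scaled
    real-part distributions, complex-plane histograms), and a
    connectivity-matched sparse random-matrix null ensemble for comparison
    with evolved spectra.
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
    withr,
    optparse
Config/testthat/edition: 3
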