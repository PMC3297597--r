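Package: fearbold
Title: Stochastic Individual-Based Simulation of Fearful and Bold
    Anti-Predator Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based stochastic simulation of the evolutionary
    dynamics of two pure anti-predator strategies, fearfulness and boldness,
    in a constant-size asexual population with overlapping generations.
    Sequential predator attacks share risk between the phenotypes either in
    proportion to their abundances (frequency-dependent) or independently of
    population structure; survivors reproduce at the end of each breeding
    season in proportion to their remaining energy reserves, optionally
    weighted by a Lotka-Volterra-style competitive background fitness that
    permits coexistence.  Provides run-to-fixation replicate experiments
    with binomial confidence intervals, parameter sweep drivers, fixed-length
    coexistence trajectory experiments, and an exact absorbing-Markov-chain
    solver for small non-overlapping-generation populations that serves as a
    brute-force verification oracle for the simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
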