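Package: kincomp
Title: Kin Selection, Competitive Effort and Inequality in Class-Structured
    Populations with Fluctuating Resources
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytical and simulation tools for the evolution of
    condition-dependent competitive effort in an infinite-island population
    whose patches switch between resource-rich and resource-poor states
    under a temporally autocorrelated two-state Markov process. Provides
    equilibrium relatedness from patch-type-conditioned recursions,
    class-structured reproductive values from the fitness-matrix
    eigen-system, neighbour-modulated selection gradients, an exact
    Hamilton's-rule decomposition into primary cost, primary benefit and
    kin-competition cost, a convergence-stable ESS solver for the four
    (or eight) conditional traits, within- and between-group inequality and
    productivity metrics, model extensions for early-life quality
    acquisition and larger patch sizes, and a finite-population
    individual-based simulator used as a stochastic cross-check of the
    analytical predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
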