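Package: breedgrad
Title: Differentiable Breeding-Scheme Simulation and Gradient-Based
    Mate-Allocation Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-generation recurrent-selection breeding simulator in
    which progeny allocation across diallel mating pairs is a parametric
    softmax over pair "goodness" metrics (weighted breeding value and
    expected genetic variance of progeny), mating-pair sampling is relaxed
    with the Gumbel-Softmax reparameterization, and per-generation
    allocation weights are optimized by stochastic gradient ascent on the
    expected top-K genetic merit of the final population.  Gradients are
    obtained by reverse-mode automatic differentiation through the whole
    scheme; a discrete simulator evaluates optimized strategies, and
    finite-difference and grid diagnostics validate the gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
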