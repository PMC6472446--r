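Package: codiv
Title: Bayesian Inference of Shared Divergence Times from Biallelic
    Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Full-likelihood Bayesian comparative phylogeography for
    multiple pairs of diverged populations. Computes the exact probability
    of biallelic allele-count patterns under the two-population
    multispecies coalescent by analytic integration over gene trees,
    places a Dirichlet-process prior over divergence models (the partition
    of pairs into shared divergence events and the event times), and
    samples the joint posterior by Markov chain Monte Carlo with Gibbs
    updates over the partition. Includes corrections for excluded constant
    characters, a coalescent simulator of binary character matrices (with
    linked loci, missing data, and singleton acquisition-bias
    perturbations), posterior summarization with Bayes factors and
    convergence diagnostics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    ape,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
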