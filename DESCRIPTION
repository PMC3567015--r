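Package: codiverge
Title: Hierarchical ABC Tests of Simultaneous Divergence Across
    Biogeographic Barriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-phylogeographic test of simultaneous versus
    non-simultaneous divergence of co-distributed taxon pairs across a
    shared biogeographic barrier, using hierarchical Approximate Bayesian
    Computation. Includes a two-population isolation-with-migration
    structured-coalescent simulator with finite-sites HKY mutation,
    population-genetic summary statistics (nucleotide diversity,
    Watterson's theta, Tajima's D, net divergence, Tamura-Nei corrected
    distances), rejection sampling with optional local-linear and
    multinomial-logit regression adjustment for the hyperparameters
    (number of divergence pulses Psi and the dispersion index
    Omega = Var(tau)/E(tau)), and a synthetic-study generator with
    known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    jsonlite,
    nnet,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
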