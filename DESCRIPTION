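Package: signedgroups
Title: Group Model for Signed Directed Ecological Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extends the group model (stochastic block model) to signed
    directed networks such as ecological interaction webs. Species are
    partitioned into groups of ecologically equivalent taxa by maximizing
    an analytically integrated Beta-Bernoulli marginal likelihood over
    per-block connection and sign probabilities. Partition space is
    searched with a collapsed Gibbs sampler embedded in Metropolis-coupled
    MCMC (parallel tempering), with exact exhaustive enumeration for small
    webs. Alternative partitions are compared with entropies, mutual
    information and a group-size-preserving randomization test, and
    interaction-type ablations (trophic-only, nontrophic-only, species
    class removals) are supported end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
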