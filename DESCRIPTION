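Package: pagmix
Title: Scalable Causal Discovery with Latent Variables on Mixed Data
Version: 0.1.0
Authors@R:
    person("pagmix", "developers", email = "pagmix@example.org", role = c("aut", "cre"))
Description: Constraint-based causal discovery for datasets that mix
    continuous and categorical variables, allowing for latent confounders.
    Implements the FCI-Stable, FCI-MAX and conservative FCI (CFCI) searches
    over partial ancestral graphs (PAGs), a regression-based conditional
    independence test for mixed data, a Lee-Hastie mixed graphical model
    (MGM) pseudolikelihood skeleton learner used to constrain the searches,
    a synthetic mixed-data generator with latent-variable removal, and a
    per-edge-type PAG evaluation scorer, so that simulation comparisons of
    the algorithm family can be run end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
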