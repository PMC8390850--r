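Package: pansoc
Title: Male Chimpanzee Sociality, Dominance and Siring Success
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking male social bonds to reproductive success in
    fission-fusion primate societies. Builds dyadic and individual sociality
    measures (simple ratio association indices from joint party arrivals,
    grooming rates, composite sociality indices) inside one-year siring
    windows, maximum-likelihood-optimized Elo dominance scores from
    pant-grunt interactions, coalition networks with betweenness, binomial
    mixed-model comparison by small-sample-corrected AIC with Akaike
    weights and a nested-model pruning rule, and a symmetric binary-probit
    social relations model of coalition formation fitted by Gibbs sampling
    with Gelman-Rubin diagnostics. Includes a synthetic community generator
    with planted bond, rank and siring effects so the entire pipeline can
    be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    lme4,
    igraph,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    coda,
    knitr
Config/testthat/edition: 3
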