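Package: bdmm
Title: Bayesian Direct Multimorbidity Maps from Binary Disease Cohorts
Version: 0.1.0
Authors@R:
    person("BDMM", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Constructs Bayesian direct multimorbidity maps (BDMMs) from
    cross-sectional cohorts of binary lifetime disease indicators.
    Pairwise comorbidity statistics (Yates-corrected chi-squared, odds and
    risk ratios with confidence intervals, the phi coefficient, logistic
    regression, Ward clustering) are computed alongside posterior
    probabilities of direct ("co=morbid") and structural (d-connected)
    disease-disease relations obtained by Markov chain Monte Carlo over
    Bayesian-network structures with BDeu scoring and Bayesian model
    averaging. Relations are classified as direct, mediated or
    parametric-only, and cross-compared with molecular-level measures:
    hypergeometric gene-set overlap and the interactome-based separation
    score. A simulator generates multimorbidity cohorts with known
    ground-truth structure, sex/age confounding and disease onset ages for
    validation and benchmarking, and a command-line driver binds the steps
    into reproducible runs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
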