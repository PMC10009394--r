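Package: dbncausal
Title: Dynamic Bayesian Networks and Posterior Intervention Effects for
    Longitudinal Symptom Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian structure learning of stationary two-slice dynamic
    Bayesian networks over binary symptom indicators from longitudinal
    panel data, and posterior distributions of do-calculus intervention
    effects between adjacent time-slices.  Provides Bayesian-Dirichlet
    (BDeu) marginal-likelihood scoring with precomputed parent-set score
    tables, a partition Markov chain Monte Carlo sampler over constrained
    transition networks (with an exhaustive-enumeration oracle for small
    problems), exact do-calculus effect computation on the unrolled
    two-slice network propagating both structure and parameter
    uncertainty, a synthetic five-wave cohort generator with monotone
    attrition, and reporting of effect-distribution grids and consensus
    graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
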