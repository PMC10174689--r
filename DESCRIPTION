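Package: rlwm
Title: Reinforcement Learning and Working Memory Modeling of Stimulus-Response Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the joint contribution of reinforcement
    learning (RL) and working memory (WM) to stimulus-response association
    learning. Implements the RL-WM task design with pseudo-randomized
    stimulus sequences, the hybrid RL-WM generative model (delta-rule
    Q-learning with asymmetric learning rates, one-shot decaying working
    memory, set-size-dependent policy mixture and lapses), hierarchical
    Bayesian estimation of the model by adaptive MCMC in three hierarchy
    variants with WAIC comparison and convergence diagnostics, parameter
    recovery and posterior predictive checks, model-independent trial-level
    logistic regressions of learning, and a cross-validated elastic-net
    pipeline linking regional neurochemical measures (e.g. prefrontal
    glutamate) to model parameters, including anatomical-specificity
    regressions and bootstrap mediation. A synthetic-cohort generator
    emulating a two-age-group study makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
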