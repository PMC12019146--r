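Package: rlddm
Title: Reinforcement-Learning Drift-Diffusion Models of Letter-Speech-Sound Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Tools for modelling feedback-driven audiovisual associative
    learning (letter-speech-sound style tasks) with reinforcement-learning
    drift-diffusion models (RLDDM). Provides the deterministic model core
    (delta-rule associative updates, trial-wise drift and decision boundary,
    six model variants), a numerically stable Wiener first-passage-time
    likelihood, hierarchical Bayesian estimation by adaptive MCMC with
    convergence diagnostics, WAIC model comparison, trial-wise posterior
    series for model-based fMRI regressors, a forward simulator for task
    cohorts, and dataset validation, binned learning summaries and group
    contrasts, with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
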