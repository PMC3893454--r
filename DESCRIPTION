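Package: twostepr
Title: Simulation and Analysis of the Two-Step Sequential Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the balance between model-based and
    model-free control of choice in the two-step sequential decision task.
    Provides the task environment (probabilistic stage transitions and
    bounded random-walk reward probabilities), hybrid reinforcement-learning
    agents mixing SARSA(lambda) with one-step planning, simulation-based
    screening of candidate reward walks, the 1-back stay/switch
    quantification of controller influence, hierarchical logistic regression
    with chi-square site contrasts, paired permutation tests for differences
    between dependent correlations, working-memory capacity (Cowan's K), and
    a synthetic-cohort generator with parameter-recovery reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
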