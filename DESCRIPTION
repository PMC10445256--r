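Package: reactbo
Title: Batch Bayesian Optimization of Enzymatic Reaction Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative batch Bayesian optimization of continuous reaction
    conditions (substrate, enzyme loading, pH, cosolvent, cofactor) against a
    scalar figure of merit such as the total turnover number (TON). Provides a
    Matern-5/2 Gaussian-process surrogate with multi-restart marginal-likelihood
    fitting, the expected-improvement acquisition function and two batch-aware
    variants: distance-based candidate exclusion on standardized scales (BOA-1)
    and a variance-squared acquisition on a max-10 rescaled response (BOA-2),
    plus a probability-of-feasibility factor for constraining a second figure of
    merit such as chemoselectivity. Includes Kriging-believer batch selection,
    a CSV experiment ledger for human-in-the-loop campaigns, a closed-loop
    driver with a mechanistic synthetic enzyme-response simulator, and a
    face-centred central-composite-design quadratic response-surface baseline
    for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
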