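Package: aseval
Title: Ancestral State Estimation and Model Evaluation for Hierarchical
    Discrete Characters on Time-Scaled Fossil Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workbench for marginal ancestral state estimation of complex
    discrete characters on a-posteriori time-scaled fossil phylogenies.
    Provides equal and minimum-branch-length time-scaling from first/last
    appearance data, rate-matrix templates for standard Mk models (equal,
    symmetric and all-rates-different schemes; ordered and unordered),
    embedded-dependency amalgamations, structured Markov models with hidden
    states, and hidden-rates expansions; Felsenstein pruning likelihoods,
    maximum-likelihood rate fitting and marginal ancestral reconstruction;
    and a model-evaluation layer with AIC/AICc, raw uncertainty, mutual
    information, leave-one-out cross-validation, Akaike and error-based
    model averaging. Includes a synthetic-data generator emulating
    feather-like hierarchical characters on birth-death fossil trees, and a
    pipeline orchestrating outgroup, time-scaling, coding-strategy and
    model-grid experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
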