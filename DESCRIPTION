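Package: navfield
Title: Position-Heading Tuning Fields and Bayesian Population Decoding for
    Virtual Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing cortical population activity recorded while
    an animal navigates a visually guided virtual T-maze. Implements
    occupancy-regularized, Gaussian-smoothed estimation of per-neuron
    position-heading tuning fields with 10-fold cross-validated bandwidth
    selection; nested comparison of position-heading, position-decision and
    position-heading-decision response models with an auROC-based confound
    exclusion; grid-based Bayesian maximum a posteriori decoding of the
    animal's trajectory from population activity under a Gaussian response
    model; psychometric and neurometric two-alternative forced-choice
    analyses; and a seeded synthetic-session generator that emulates the
    behavioral and neural statistics these analyses assume, so the whole
    pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
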