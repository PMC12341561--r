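Package: deltadyn
Title: Delta-Learning Composite Potentials and Quasi-Classical Trajectory Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A framework for composite machine-learning interatomic
    potentials built as a semi-empirical baseline plus an ensemble of
    neural-network delta-corrections plus a pairwise dispersion term.
    Provides atomic environment vector descriptors with analytical first
    and second derivatives, two-stage ensemble training with transfer
    learning and frozen layers, ensemble uncertainty quantification,
    geometry and transition-state optimization with harmonic frequency
    analysis, quasi-classical trajectory dynamics with harmonic quantum
    Boltzmann sampling, product-branching analysis for bifurcating
    reactions, and benchmark-style error metrics.  Ships synthetic
    potential-energy-surface generators so the full pipeline is testable
    without external quantum-chemistry programs or datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
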