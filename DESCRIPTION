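Package: hierDediff
Title: Selection for De-Differentiation in Hierarchical Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Matrix population models of hierarchically structured cell
    populations (stem cells through terminally differentiated cells) in which
    mutant cells can de-differentiate, either stepwise to the adjacent
    upstream compartment or jumpwise directly back to the stem-cell
    compartment. Builds the resident and mutant projection matrices, computes
    dominant-eigenvalue fitness and spectral summaries, evaluates selection
    gradients for de-differentiation by three independent routes (closed-form
    Gamma expressions, eigenvalue perturbation with left/right eigenvectors,
    and exact eigenvalue differences at finite de-differentiation rates),
    solves for critical redistributing factors and critical division rates at
    which the selection gradient changes sign, propagates deterministic
    compartment dynamics by matrix-exponential action, and drives parameter
    scans and invasion-boundary tracing from a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'params.R'
    'fixtures.R'
    'random-params.R'
    'matrices.R'
    'spectral.R'
    'gradients.R'
    'thresholds.R'
    'dynamics.R'
    'scan.R'
    'io.R'
    'cli.R'
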