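Package: nscpatterns
Title: Spatiotemporal Statistics and Simulation of Neural Stem Cell
    Division Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of dividing neural stem cell (NSC) populations on the
    ventricular surface of the adult zebrafish telencephalon. Implements
    discrete Ripley's K statistics on cell-position point clouds with
    Monte-Carlo sampling envelopes and aggregated/random/dispersed
    classification, a two-parameter interaction (placement) model for the
    spatiotemporal dependence of successive S-phases with maximum-likelihood
    fitting and posterior sampling, a nonspatial cell-division model with
    lag-exponential cell-cycle and S-phase lengths fitted to double-labeling
    data by approximate Bayesian computation, and an agent-based simulator of
    a growing NSC sheet with cell-cycle reentry (redivision). A synthetic-data
    module generates hemispheres and labeled division patterns with known
    ground truth so every pipeline stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
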