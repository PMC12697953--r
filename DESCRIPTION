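Package: uatrack
Title: Uncertainty-Aware Cell Tracking for Microbial Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic frame-to-frame lineage inference for 2D monolayer
    colonies of rod-shaped bacteria. Appearance, disappearance, migration and
    division hypotheses are scored with composable statistical models of cell
    behaviour (movement, area growth, orientation, division geometry), an
    optimal set of assignments is selected per frame pair by an exact-cover
    branch-and-bound optimiser, and a particle filter maintains a distribution
    over cell lineage trees. Includes a stochastic colony simulator with ground
    truth lineages, Cell Tracking Challenge track-file input/output, and
    evaluation metrics (division F1, AOGM-style linking score).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
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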