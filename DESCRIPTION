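Package: cabnet
Title: Combined Competitive, Attractor and Backprojection Network Model of
    Neocortical Pyramidal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rate-model simulation of a single population of binary neocortical
    pyramidal cells that simultaneously self-organises three computations with
    one Hebbian rule and whole-dendrite synaptic weight normalization:
    categorisation of correlated forward inputs by competitive learning,
    short-term memory through recurrent-collateral attractor dynamics, and
    top-down recall and attentional biasing through backprojection pattern
    association. Includes generators for the overlapping forward and orthogonal
    backprojection training pattern sets, correlation diagnostics, experiment
    protocols (categorisation, attractor persistence, recall fidelity,
    attention biasing, multi-seed statistics, parameter-robustness sweeps),
    delimited-text persistence of patterns, weights and reports, and a small
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
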