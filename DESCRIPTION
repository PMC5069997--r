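Package: dualpf
Title: Dual Partition Function and Boltzmann Sequence Sampling for RNA
    Inverse Folding
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the dual partition function Z* over all RNA
    sequences compatible with a target secondary structure under the
    Turner nearest-neighbour energy model, with per-position IUPAC
    sequence constraints, exact GC-content resolution, and exact
    Boltzmann-weighted sequence sampling by stochastic backtracking.
    Also provides dual thermodynamic quantities (dual ensemble free
    energy, dual expected energy, dual entropy, dual heat capacity),
    a standalone loop-model energy evaluator, and structure-ensemble
    metrics (ensemble diversity, plasticity, ensemble distance,
    mutational robustness, neutrality) on top of pluggable secondary
    structure folding backends.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
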