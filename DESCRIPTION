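Package: fmdd
Title: Fuzzy Multiobjective Drug-Target Discovery on Power-Law Kinetic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying enzyme drug targets in generalized
    mass-action (GMA) kinetic models of metabolism. Provides a power-law
    kinetic engine (rate evaluation, damped-Newton steady-state solving in
    log space with ODE-integration fallback, deficiency perturbations,
    fold-change reports), fuzzy membership functions that grade therapeutic,
    adverse and target-variation effects on a 0-1 satisfaction scale, a
    max-min decision problem with a target-count penalty, and a nested
    hybrid differential evolution (NHDE) search that evolves integer-coded
    target subsets, each evaluated by an inner continuous solve. Ships a
    synthetic presynaptic dopamine network with disease scenarios (VMAT2 and
    tyrosine hydroxylase deficiencies) and Parkinson's-disease drug presets,
    plus generators for random consistent GMA networks used in testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    lhs,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    pkgload,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
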