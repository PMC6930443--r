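Package: clickassembly
Title: Intransitive Click Assemblies of Immune Cell Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates "click assemblies": directed kill-cycles of immune
    cell populations in which specialized receptor-ligand pairs (clicks)
    trigger the contextual death of exactly one partner. Provides assembly
    definition and validation under the two click rules (pair exclusivity,
    directional killing), reduction to the smallest directed kill cycle,
    deterministic mean-field dynamics via generalized Lotka-Volterra ODEs,
    a stochastic spatial cellular automaton on a toroidal lattice, regime
    diagnostics (attractor classification, bystander-help bifurcation
    scans, return maps, twin-trajectory Lyapunov estimates, basin
    sampling), and an exact Efron-dice tournament engine embodying the
    underlying intransitive logic.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    igraph,
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
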