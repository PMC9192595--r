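Package: quadfret
Title: Single-Molecule FRET Analysis of G-Quadruplex Conformational Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for two-channel single-molecule FRET
    recordings of telomeric G-quadruplex folding dynamics and protein
    binding. Covers trace input/output with photobleach truncation, FRET
    efficiency histograms with anchored multi-Gaussian decomposition and
    differential density analysis, hidden-Markov state-path inference with
    2-4 state selection, transition-density and dwell-time statistics
    including the NP-P direct-transition-density metric, one-site
    dissociation-constant regression on binding titrations, and a
    continuous-time Markov simulator of donor/acceptor trajectories that
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
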