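Package: olmens
Title: Ensemble Modeling of Hippocampal O-LM Interneuron Conductances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale cyclical ensemble modeling of hippocampal
    oriens-lacunosum/moleculare (O-LM) interneurons. Simulates grids of
    conductance-based multi-compartment model variants under current-clamp,
    voltage-clamp and mixed protocols, extracts electrophysiological
    measures from the voltage traces, ranks model variants against an
    experimental-style dataset with a normalized z-score distance, extracts
    subsets of appropriate models via derivative-based and
    representative-measure cutoffs, and analyzes conductance co-regulations
    with clutter-based dimensional stacking and pairwise conductance
    histograms. Includes a calibrated synthetic surrogate for the
    experimental current-clamp dataset.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils,
    tools,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
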