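Package: fconnet
Title: EEG Functional Brain Networks Across Connectivity Estimators and
    Binarization Methods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for constructing and comparing EEG-based functional
    brain networks. Computes weighted connectivity matrices with four
    dependency estimators (Pearson correlation, band-averaged coherence,
    Hilbert phase order parameter, and synchronization likelihood),
    binarizes them by uniform threshold, fixed density, minimum spanning
    tree (MST) or minimum connected component (MCC), evaluates six
    graph-theory metrics (global and local efficiency, node and edge
    betweenness centrality, modularity, assortativity), and compares two
    subject groups point-by-point with Wilcoxon's rank-sum test over
    binarizer parameter sweeps. Includes a seeded synthetic resting-EEG
    cohort generator with planted coupling graphs so every stage is
    testable without clinical recordings, plus preprocessing (epoching,
    voltage/transition artifact rejection, common average reference,
    zero-phase FIR band-pass).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
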