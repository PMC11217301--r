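Package: dfctools
Title: Temporal Stability and Community Architecture of Dynamic Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-branch characterization of resting-state functional
    connectomes from parcellated BOLD-like timeseries. The temporal branch
    estimates dynamic functional connectivity by instantaneous phase
    coherence, extracts the dominant subspace of each time-resolved
    connectivity pattern, builds a time-by-time temporal-stability
    ("landscape") matrix of principal angles, and summarizes it by histogram
    entropy and global temporal distance at whole-brain and per-network
    level. The spatial branch fits a weighted stochastic block model to the
    Fisher-z static connectivity matrix by variational Bayes with
    multi-restart selection, then classifies community-pair interactions
    into assortative, core-periphery and disassortative motifs, with
    diversity indices, regional assortativity scores and morphospace
    coordinates. Includes synthetic generators for planted block-model
    graphs and phase-coupled oscillatory cohorts, a normality-gated
    group-comparison protocol with covariate residualization, file I/O for
    delimited-text exchange formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
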