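Package: triplenet
Title: Static and Dynamic Functional Network Connectivity in the Triple-Network Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for static and dynamic functional network
    connectivity (FNC) among independent-component time courses of the
    triple-network model (default mode, executive control and salience
    networks). Implements time-course post-processing (polynomial
    detrending, nuisance regression with temporal derivatives, low-pass
    filtering, despiking), Fisher-z static FNC, tapered sliding-window
    dynamic FNC, k-means brain-state analysis with elbow-criterion model
    selection and temporal statistics (reoccurrence fraction, dwell time,
    transition counts), multilayer-network community detection by
    generalized Louvain modularity maximization with module-allegiance and
    integration summaries, and group statistics (GLM with covariates,
    Benjamini-Hochberg FDR families, brain-behavior correlations). A
    synthetic-data generator produces state-switching multivariate time
    courses and cohorts with known ground truth so the full pipeline is
    exercisable and testable without MRI data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
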