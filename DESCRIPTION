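Package: tsync
Title: Transient Synchronization Analysis of Resting-State fMRI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transient brain-wide synchronization events in
    resting-state BOLD time series with sliding-window principal component
    analysis, clusters the resulting synchronization patterns with
    correlation-distance k-means and pairs anti-correlated sub-clusters via
    their transition structure, reconstructs voxel-level synchronized
    activation maps with an event-coded GLM using the canonical
    haemodynamic response, characterizes the temporal structure of cluster
    co-occurrence with pointwise mutual information, validates results
    against phase-randomized stationary surrogates, and relates
    synchronization patterns to static functional connectivity and subject
    measures through permutation-tested canonical correlation analysis.
    Includes a synthetic-data generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    RNifti,
    jsonlite,
    igraph,
    cluster
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
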