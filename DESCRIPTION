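Package: dynconn
Title: Dynamic Functional Network Connectivity States and Topological Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of dynamic functional network connectivity from
    independent-component time courses: motion quality control with Jenkinson
    framewise displacement, time-course post-processing (detrend, despike,
    Butterworth low-pass, nuisance regression), tapered sliding-window
    connectivity via L1-penalised precision matrices with Fisher z transform,
    k-medians clustering of windowed connectivity into recurring states with
    occupancy, dwell-time and transition statistics, Louvain modularity with
    consensus clustering of state centroids, dynamic graph-topology variability
    (coefficient of variation of the area under the curve of efficiency and
    small-world metrics over sparsity thresholds), and covariate-adjusted
    permutation tests with false-discovery-rate control. Includes a Markov
    state-switching multivariate Gaussian cohort simulator with full ground
    truth for recovery experiments.
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
    tools,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
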