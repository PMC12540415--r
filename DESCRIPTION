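Package: calnet
Title: Functional Network Topology from Calcium Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-animal functional connectivity networks from two-photon
    calcium imaging fluorescence traces and characterizes their topology under
    paired stimulation conditions. Provides trace preprocessing (background
    subtraction, exponential detrending, scaling, variance/maximum-response
    quality control, Savitzky-Golay smoothing, min-max normalization),
    correlation-based weighted network construction, from-scratch weighted
    graph measures (betweenness, closeness and degree centrality, global
    efficiency, Louvain community detection with resolution-parameterized
    modularity), exact Wilcoxon signed-rank paired comparisons across animals,
    hub response-hierarchy analysis, and a synthetic paired-condition
    calcium-trace generator with controllable hub-centric or distributed
    latent coupling for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
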