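Package: hdinet
Title: Hub Disruption Analysis of Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of resting-state functional connectomes:
    grey-matter-weighted parcel time-series extraction, motion/artifact
    quality control with nuisance regression, maximal overlap discrete
    wavelet transform (MODWT) correlation at dyadic frequency scales,
    minimum-spanning-tree anchored cost thresholding into connected
    unweighted graphs, nodal graph metrics (degree, clustering, local
    efficiency, betweenness centrality), the hub disruption index (HDI)
    against a reference cohort, and the group-level statistical layer
    (nonparametric rank tests, Fisher exact test, linear mixed-effects
    longitudinal model with cluster bootstrap intervals, node-wise
    exploration with multiple-comparison correction). Ships a seeded
    synthetic-cohort generator emulating hub-structured connectomes,
    band-limited BOLD-like time series, hub-disrupted patient networks,
    motion traces, and longitudinal HDI tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    lme4,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
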