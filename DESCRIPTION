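Package: echoscape
Title: Pelagic Seascape Classification from Echosounder Scattering Layers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to characterise pelagic seascapes from dual-frequency
    scientific echosounder data. Extracts sound scattering layers (SSLs)
    from gridded volume backscattering strength (Sv) echograms by
    threshold segmentation after echo-integration, computes layer
    descriptors (depth band, width, length, mean Sv) and weighted mean
    depth, classifies day and night by solar altitude to quantify diel
    vertical migration, groups descriptor vectors into seascape clusters
    by k-means with silhouette-based selection of the number of clusters,
    and models environmental drivers of backscatter with generalized
    additive models fitted to CTD-matched records. A synthetic-scene
    generator emulating contrasting tropical ocean regimes makes every
    stage testable without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    cluster,
    geosphere,
    mgcv,
    lmtest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'echoscape-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'echogram-methods.R'
    'io.R'
    'config.R'
    'presets.R'
    'simulate.R'
    'preprocess.R'
    'layers.R'
    'diel.R'
    'cluster.R'
    'gam.R'
    'pipeline.R'
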