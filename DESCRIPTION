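Package: RadVisSeg
Title: Radial-Coordinate Visualization and Cluster Segmentation of
    Multidimensional Patient Questionnaire Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Visual-analytics engine for stratifying patient cohorts measured on
    multidimensional questionnaire batteries (e.g., the 15-item Seoul-Instrumental
    Activities of Daily Living scale across dementia diagnosis stages). Provides
    classic 2D radial-coordinate (RadVis) projection and a 3D cylindrical variant
    in which each record's horizontal position is the anchor-weighted barycenter
    of its min-max normalized values and its height is their mean, so records
    that would overlap in 2D separate along the vertical axis. Includes
    patient-patient similarity graphs (cosine, Pearson, Spearman) with threshold
    edge selection and seeded force-directed layout, Lloyd k-means with Forgy and
    Random initialization for cluster segmentation, parallel-coordinates axis
    models with multi-interval conjunctive filtering, per-cluster descriptive
    statistics, CSV export, a synthetic cohort generator emulating a staged
    dementia registry, and a batch pipeline with static HTML/SVG renders plus a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
biocViews: Visualization, Clustering, Classification
RoxygenNote: 7.3.3
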