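Package: spnatlas
Title: Cell-Type Taxonomy, Relatedness and Physiology Analysis for
    Retrogradely Labelled Projection Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building single-nucleus RNA-seq cell-type
    taxonomies of retrogradely labelled projection neurons and for the
    companion physiology and imaging read-outs. Implements quality-control
    gating with fluorophore-transcript (XFP) based first- versus
    second-order cluster classification, normalization and
    multi-resolution graph clustering, type-centroid taxonomy trees,
    gene-module scoring and LIM-group assignment, constellation
    relatedness graphs and per-nucleus KNN heterogeneity scores,
    nearest-centroid cross-taxonomy mapping with support filtering,
    detection- and fold-change-gated marker calling, projection-target
    proportion tables, spike-waveform and passive-membrane feature
    extraction from patch recordings, and axon-density contour and
    colocalization quantification from fluorescence images. A synthetic
    data module generates count matrices, recordings and images with
    planted ground truth so that every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    irlba,
    ape,
    EBImage,
    RANN,
    uwot,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
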