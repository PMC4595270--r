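Package: scqpcr
Title: Analysis and Visualisation of Single-Cell qRT-PCR Ct Data with
    Index-Sorting Integration
Version: 0.1.0
Authors@R:
    person("Molecular", "Hematology Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Import, quality control, normalisation, dimensionality reduction,
    clustering, flexible cell grouping and paired visualisation for single-cell
    qRT-PCR cycle-threshold (Ct) data, with optional integration of FACS
    index-sorting surface-marker intensities keyed by well ID. Supports
    Fluidigm-Biomark-style table and heatmap exports as well as generic Ct
    matrices, limit-of-detection inversion, housekeeping-median scaling,
    z-transformation, PCA/Isomap/LLE embeddings, correlation-distance
    hierarchical clustering and k-means, gate- and cutoff-based cell grouping,
    and reproducible ZIP session archives with an append-only analysis log.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
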