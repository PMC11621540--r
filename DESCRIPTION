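Package: spatialTME
Title: Spatial Tumor-Microenvironment Scoring, Trajectory Landscapes and
    Region Detection for Hexagonal-Lattice Spatial Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the tumor microenvironment (TME) in
    spatial transcriptomics sections on a hexagonal spot lattice.
    Implements per-spot signature enrichment scoring (PAGE statistic) and
    module scores, spot classification into TME features, spatial
    trajectory landscapes with detection of coordinated TME changes and
    the signed cor_st association score, distance-weighted local
    enrichment with connected-region calling of possibly malignant
    regions, binary-mask image registration between imaging modalities by
    IoU maximisation, and preprocessing of segmented-cell marker
    intensity tables (percentile outlier filtering, CLR normalisation).
    A synthetic-data module generates Visium-like sections, mask pairs
    and cell tables with recorded ground truth so every stage is testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, Matrix, S4Vectors, jsonlite, igraph,
    png, tiff, EBImage
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Spatial, Transcriptomics, GeneExpression
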