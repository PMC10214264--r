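Package: cytoBench
Title: Benchmarking Preprocessing Workflows for Cytometry-Based Single-Cell Proteomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cytometry-based single-cell proteomics (CySCP) data through an
    enumerable space of 1125 four-step preprocessing workflows (compensation,
    transformation, normalization, signal cleaning), evaluates every workflow under
    independent criteria for cell-subpopulation-identification (CSI) and pseudo-time
    trajectory-inference (PTI) studies, and produces a categorized, weighted overall
    ranking identifying optimal workflows. Includes FCS 3.0/3.1 input/output, a
    registry of 25 preprocessing methods with flow/mass-cytometry applicability,
    seeded synthetic-data generators with known ground truth, and a parallel
    workflow scanner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    cluster,
    mclust,
    glmnet,
    igraph,
    pracma,
    e1071,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
biocViews: FlowCytometry, Proteomics, SingleCell, Preprocessing, QualityControl
RoxygenNote: 7.3.3
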