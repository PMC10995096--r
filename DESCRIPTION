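Package: lqci
Title: Urban Blue-Green Landscape Quality Assessment with a GA-BP Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the composite quality of urban blue-green
    (water and vegetated) landscapes from yearly indicator series and
    categorical land-cover rasters. Computes the six class-level landscape
    pattern metrics (NP, PD, AREA_MN, LPI, LSI, AI) from integer rasters,
    derives indicator weights by the analytic hierarchy process (AHP),
    builds a min-max normalized, weight-summed Landscape Quality Composite
    Index (LQCI) with ordinal level classification, and fits a 17-6-1
    feed-forward neural network whose initial weights are searched by a
    real-coded genetic algorithm before backpropagation refinement (GA-BP).
    Model quality is judged by standard regression error metrics and
    leave-one-out cross-validation. Ships the study's printed indicator
    tables as fixtures plus seeded generators for synthetic indicator
    series and rasters with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
biocViews: Regression, Classification, Spatial
RoxygenNote: 7.3.3
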