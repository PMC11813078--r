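Package: ethospan
Title: Long-Timescale Behavior Quantification for Individual Flies
Version: 0.1.0
Authors@R: person("Ethospan", "Developers", email = "maintainers@ethospan.dev",
    role = c("aut", "cre"))
Description: A pipeline for quantifying stereotyped behavior of individually
    housed Drosophila melanogaster over multi-day recordings. Takes keypoint
    pose tracks (14-node skeleton), cleans and egocentrizes them, computes
    rolling Lomb-Scargle spectral features that tolerate missing samples,
    builds a two-dimensional behavioral map (UMAP embedding plus kernel
    density segmentation), assigns per-frame ethogram labels, models bout
    dwell times with a two-component geometric mixture, and analyses the
    resulting behavior compositions with log-ratio geometry and robust
    (Minimum Covariance Determinant) principal components. Ships a synthetic
    fly generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    FNN,
    igraph,
    uwot,
    jsonlite,
    yaml,
    withr,
    rhdf5
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
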