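Package: spotdecon
Title: Deconvolution and Single-Cell Decomposition of Spot-Based Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates cell-type composition of sequencing-based spatial
    transcriptomics spots from an annotated single-cell reference via a
    multinomial generative model with gene-wise batch-effect parameters,
    decomposes each spot's counts into inferred single-cell expression
    profiles, and imputes proportions and profiles for nuclei outside the
    capture areas with Gaussian-process regression. Includes a synthetic
    data generator with ground truth and the standard per-spot proportion
    metrics (absolute error, square error, Jensen-Shannon divergence,
    Pearson correlation, cosine similarity, fraction correctly mapped) so
    the whole pipeline can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
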