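Package: samoco4d
Title: Single-Angle-Based Motion Compensation for 4D Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gating-free respiratory motion compensation for slowly rotating
    cone-beam CT. Implements single-angle filtered backprojections (SARs),
    FDK reconstruction with shifted-detector redundancy weighting, backward
    trilinear warping of SARs with displacement vector fields (DVFs), the
    SAMoCo warped-sum reconstructor with single-view temporal resolution,
    retrospectively gated reconstruction, compact trainable 3D U-Nets for
    DVF prediction from modified SAR pairs and for residual streak-artifact
    correction, a deformable 10-phase digital thorax phantom with exact
    analytic inter-phase DVFs and anatomical class labels, cone-beam scan
    simulation with periodic and non-periodic breathing signals, and
    evaluation tools (sigmoid-fitted diaphragm tracking, anatomy-specific
    DVF statistics, HU accuracy metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
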