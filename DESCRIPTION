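Package: tractwise
Title: Longitudinal Along-Tract Analysis of White-Matter Fractional Anisotropy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A desk-scale tractometry pipeline for longitudinal diffusion
    tensor imaging studies of white-matter integrity. Simulates multi-wave
    diffusion-weighted phantom cohorts with known fiber geometry and known
    fractional anisotropy (FA) time courses, reconstructs diffusion tensors
    by log-linear least squares, performs deterministic streamline
    tractography (fiber assignment by continuous tracking, FACT), extracts
    seed-to-target fiber bundles from label volumes, parameterizes each
    bundle into 100 equidistant along-tract FA segments, and computes
    longitudinal change statistics: per-subject annual percentage FA change,
    outlier exclusion, paired t-tests, repeated-measures ANOVA, Bonferroni
    correction and segment-wise along-tract testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    minpack.lm
Config/testthat/edition: 3
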