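Package: hdrshape
Title: Group-Level Testing of Hemodynamic Response Shape from Multiple
    Basis Functions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Group analysis of hemodynamic response (HDR) profiles estimated
    at the subject level with multiple basis functions (TENT/FIR or
    canonical-plus-derivative sets). Fits the multivariate linear model
    B = XA + D across subjects and provides the major test families for
    HDR shape: whole-profile multivariate tests (Hotelling T-squared,
    Pillai/Wilks), effect-by-component interaction tests in univariate
    (sphericity-corrected repeated-measures) and multivariate forms,
    dimension reductions (area under the curve, Euclidean norm), and a
    linear mixed-effects omnibus test for a single group. Includes an
    AR(1) multivariate-Gaussian simulator of per-subject component
    estimates and a Monte-Carlo study driver that estimates false-positive
    rate and power of each test across scenarios and sample sizes, plus
    long-format table input/output and a voxelwise NIfTI driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    lme4,
    lmerTest,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
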