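Package: crcestr
Title: Creatine CEST MRI Analysis of Skeletal-Muscle Oxidative Capacity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for creatine chemical exchange saturation transfer (CrCEST)
    MRI studies of skeletal-muscle oxidative phosphorylation capacity. Covers
    the full exercise-recovery pipeline: a synthetic phantom generator with a
    two-pool Lorentzian z-spectrum forward model and known creatine kinetics;
    WASSR-based per-voxel B0 mapping, offset interpolation and B1 correction;
    MTR asymmetry maps; muscle-ROI time series with resting CrCEST, exercise
    delta-CrCEST and exponential recovery time constant (tauCr) fitting with
    plausibility filtering; and the cohort statistical layer (rank tests,
    mixed-effects and per-muscle linear model suites) with synthetic cohort
    generators for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
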