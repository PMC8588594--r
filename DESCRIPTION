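Package: t2demu
Title: Random-Forest Emulation of a Type-2-Diabetes Trajectory Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a time-as-input random-forest emulator for weekly
    26-week trajectories of body mass index, fasting glucose and TNF-alpha
    produced by a patient-specific type-2-diabetes simulator. Provides the
    discrete virtual-subject design space (46170 initial conditions), a
    stratified Latin-hypercube subsampler, an energy-balance model (REE,
    AEE, thermic effect of food) defining per-meal macronutrient levels, a
    stochastic surrogate simulator used as stand-in ground truth,
    bootstrap-residual confidence bands with coverage probability, per-week
    RMSE evaluation on unit-scaled outputs across training-set sizes, and a
    constrained diet optimizer that minimizes emulated inflammation subject
    to per-meal macronutrient bounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
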