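Package: veplink
Title: Linking Visual Evoked Potentials to Behavioral Sensitivity to Cue
    Reliability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for behavioral-neurometric linking analyses of visual
    evoked potentials (VEPs) in cue-reliability psychophysics. Generates
    Gaborized ellipse displays with independently controlled contour and
    surface cue reliability, fits and inverts four-parameter probit
    psychometric functions, transforms accuracy to d-prime and fits the
    log-log d-prime/jitter linking model, runs mass-univariate regression
    of rectified single-trial EEG amplitudes on cue jitter with
    spatiotemporal cluster-based permutation inference and retention of
    points matching the behavioral slope confidence interval, performs
    peak-aligned evoked-component mixed-model regression, and decodes
    stimulus orientation per timepoint with shrinkage-regularized linear
    discriminant analysis and activation-pattern projection. Includes
    seeded synthetic-data generators (behavior and multi-channel epochs)
    with known ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite,
    lme4,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), nortest
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
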