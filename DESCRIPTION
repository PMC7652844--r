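Package: relbeta
Title: Relative EEG Beta-Band Power as a Sex Biomarker
Version: 0.1.0
Authors@R:
    person("relbeta", "maintainers", email = "relbeta@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for validating relative EEG
    beta-band power (12-25 Hz) as a biomarker of biological sex. Provides a
    seeded synthetic EEG cohort generator with a controllable sex effect on
    beta amplitude, paired pre/post sessions and injectable artifacts; a
    PREP-style cleaning chain (flat-channel and low-correlation channel
    detection, artifact subspace reconstruction, windowed rejection,
    spherical-spline interpolation, average re-referencing, zero-phase
    filtering); Welch band-power features; univariate and multivariate
    logistic classifiers evaluated with balanced-subsample averaged ROC
    curves, constrained maximum accuracy and leave-one-out cross-validation;
    and the accompanying non-parametric group statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
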