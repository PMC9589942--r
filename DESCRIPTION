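Package: crfdk
Title: Optimal Experimental Design for Contrast Response Function Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and validating contrast response function (CRF)
    experiments in visual neurophysiology. Implements Naka-Rushton curve
    evaluation and bounded multistart least-squares fitting, an inhomogeneous
    Poisson spike-train simulator, three fit-error estimators (RMS at sampled
    contrasts, RMS over the full curve, and the angle between parameter
    vectors), ten linear and logarithmic contrast-spacing scales, a Monte-Carlo
    sweep over experimental-condition "patterns" (number of contrast points,
    number of trials, trial length) with a fit-quality versus recording-time
    trade-off analysis, and a ground-truth subsampling pipeline that scores,
    ranks and aggregates patterns on rich recordings, including a growing-window
    analysis of fit stability. A synthetic-cohort generator emulating a
    cat visual-cortex protocol (24 contrasts, 50 repetitions, 4 s trials)
    provides a fully reproducible test substrate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
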