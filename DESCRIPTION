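Package: spindlepp
Title: Point-Process GLM Analysis of Sleep Spindle Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models moment-to-moment sleep spindle timing as a discrete-time
    point process. The conditional intensity (instantaneous spindle density)
    is a log-linear function of sleep stage, slow-oscillation (SO) phase,
    stage-phase interactions, quadratic SO power, SO-power-phase interactions,
    and a cardinal-spline expansion of the lag since the previous spindle.
    Provides maximum-likelihood fitting, history-modulation curves and their
    summary features (refractory period, excitatory period, peak, infraslow
    multiplier), phase-coupling estimates with circular confidence intervals,
    nested-model likelihood-ratio tests, deviance decomposition, a synergy
    index, time-rescaling goodness of fit, population-level comparisons
    (curve correlations, Watson-Williams tests, global permutation tests),
    and a synthetic-night generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
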