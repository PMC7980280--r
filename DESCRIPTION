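Package: ladderfp
Title: Fiber-Photometry Analysis of Cerebellar Locomotor Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking Purkinje-cell GCaMP6f fiber-photometry
    signals to adaptive locomotor learning on an automated horizontal ladder.
    Provides a synthetic-data generator emulating two-channel (signal +
    isosbestic control) recordings with conditioned-learning behavior,
    preprocessing (artifact removal, photobleaching correction,
    Savitzky-Golay control filtering, isosbestic-regressed dF/F, z-scoring),
    event-stream trial segmentation and classification, stimulus-locked
    window metrics (mean z in the CS-US window, delta-z, slope, the combined
    step-time/photometry log2 Euclidean statistic), and the group-comparison
    statistics used for cohort contrasts (mixed-effects repeated measures
    with Geisser-Greenhouse correction and Sidak contrasts, Welch's t,
    Mann-Whitney, Kruskal-Wallis with Dunn's test, Fisher's exact, Gaussian
    GLM regression, and ROUT outlier identification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    MASS,
    minpack.lm,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
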