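Package: circacage
Title: Circadian Analysis of Metabolic-Cage Behaviour in Pregnant and Non-Pregnant Mice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing circadian patterns of food intake, water
    intake, physical activity and wakefulness recorded by metabolic cages
    under a 12:12 light-dark cycle. Provides a synthetic-cohort generator
    with known circadian structure and pregnancy effects, preprocessing of
    raw per-interval records into hourly per-mouse series, a threshold-based
    dark-phase activity-onset detector with a mixed-model group comparison,
    Bayesian natural-spline multilevel models of each behaviour (conjugate
    Gibbs sampling for square-root-scale Gaussian responses, Metropolis-
    within-Gibbs for beta-distributed wake fractions), and posterior peak
    detection with credible-interval comparisons across five Zeitgeber-time
    windows.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    glmmTMB,
    lmerTest,
    lme4,
    emmeans,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    splines
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
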