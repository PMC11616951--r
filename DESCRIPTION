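Package: equilying
Title: Accelerometer-Based Analysis of Lying Behaviour in Horses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying equine recumbency from leg-mounted
    1 Hz single-axis accelerometer logs and for analysing the resulting
    day/night lying metrics from crossover experiments. Provides threshold
    classification of posture with a running-median (majority-vote) filter,
    lying-bout segmentation, per-hour day and night metrics, balanced
    crossover schedule construction, Gaussian linear mixed models with
    crossed horse and calendar-date random intercepts on log-transformed
    outcomes, parametric-bootstrap likelihood-ratio tests and factor-scale
    confidence intervals, and a synthetic-data module (alternating-renewal
    posture traces and model-structured outcome tables) that makes every
    pipeline stage verifiable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
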