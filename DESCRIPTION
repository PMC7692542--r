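Package: dyadsync
Title: Nonverbal Synchrony and Attraction Prediction from Dyadic Motion
    Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Quantifies nonverbal behavior in dyadic interactions from
    markerless motion tracking: skeletal joint and facial blendshape time
    series are interpolated to a uniform rate, low-pass filtered with a
    zero-phase Butterworth filter, reduced to extent-of-movement metrics,
    and paired into windowed lagged cross-correlation synchrony scores.
    Questionnaire-derived outcomes (interpersonal attraction composite,
    impression accuracy as profile correlation, affective valence) feed a
    candidate feature table from which correlation-based feature selection
    and support-vector-machine recursive feature elimination pick
    predictors for random-forest and multilayer-perceptron classifiers of
    high versus low interpersonal attraction.  A synthetic dyad-session
    generator with known coupling strength, lag, and latent attraction
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    nnet,
    randomForest,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
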