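Package: gaitclass
Title: Probabilistic Gait Classification from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies walking trials recorded with shank- and waist-mounted
    inertial measurement units into healthy-elderly, post-stroke and
    Huntington-like gait classes. Implements class-specific two-state
    (stance/swing) hidden Markov models with three-mode Gaussian-mixture
    emissions over seven sensor-derived channels, a 90-dimensional hybrid
    feature set combining model log-likelihoods with time- and
    frequency-domain descriptors, radial-basis-function support vector
    machine classification with a grid search maximizing the minimum
    class-specific accuracy, leave-one-subject-out cross-validation and
    majority-voting post-processing. Ships a synthetic gait cohort
    generator with exact foot-strike/toe-off annotations so the whole
    pipeline can be exercised and tested without clinical recordings.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
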