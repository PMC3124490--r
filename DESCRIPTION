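Package: likspace
Title: Likelihood-Space Analysis of Neural Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-process modelling of neural spike trains and their projection
    into a stimulus-likelihood coordinate space. Provides conditional-intensity
    likelihoods for single neurons and marked-point-process populations,
    extended Kalman filtering of spike counts across repeated trials,
    Bayes-optimal classification in the likelihood space, stimulus-specific
    information and information-based stimulus distances, time-rescaling
    Kolmogorov-Smirnov goodness-of-fit diagnostics, classical multidimensional
    scaling of stimulus dissimilarities, and an inhomogeneous-Poisson simulator
    that emulates a visual-categorisation single-unit experiment so every stage
    can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
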