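Package: oculochain
Title: Mixture and Markov-Chain Analysis of Early Saccades in Timed
    Reaction-Time Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to separate premature from anticipatory saccades in
    warned reaction-time (foreperiod) tasks. Provides a synthetic trial
    generator with latent Markov-governed trial states and state-conditional
    latency distributions, early/visual/failed trial classification with a
    breakpoint-detected or fixed latency cut-off, two-component Gaussian
    mixture decomposition of early-saccade latencies with a density-crossing
    cut, observable Markov chain estimation (maximum likelihood transition
    matrices, Markov-property testing, row uniformity tests, confidence
    intervals on probability differences), kernel density estimation and
    differencing of latency distributions, two-sample Kolmogorov-Smirnov Z
    tests, and a reproducible end-to-end pipeline with a run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
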