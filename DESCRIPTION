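Package: tistim
Title: Montage Optimization for Transcranial Temporal-Interference Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for optimizing high-definition transcranial electrical
    stimulation montages, with a focus on temporal-interference stimulation
    (tTIS). Provides an analytic multishell spherical-head forward model and a
    random smooth fixture generator for lead-field matrices, beat-envelope
    modulation and focality metrics (peak, concentration and mis-stimulation
    ratios), safety normalization of electrode currents, and three montage
    optimizers: least-squares estimation for single-frequency tACS, an
    unsupervised generator network trained by gradient descent against a
    three-ratio loss, and genetic-algorithm baselines for two-pair and
    high-definition montages. Includes study drivers for depth sweeps,
    multi-target stimulation with partitioned evaluation, and method
    comparison, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'stimulation.R'
    'optim-lse.R'
    'ga.R'
    'usnn.R'
    'experiments.R'
    'sphere.R'
    'leadfield.R'
    'cli.R'
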