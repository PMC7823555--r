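Package: p300vib
Title: P300 Speller Detection with a Variational Information Bottleneck Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation, preprocessing and classification of P300 speller
    electroencephalography (EEG). Provides an oddball-paradigm simulator for
    6x6 row/column speller trials with a P300-like deflection on target
    epochs, the standard preprocessing chain (epoch windowing, Chebyshev
    type-I bandpass, per-sample normalization, class rebalancing), a
    convolutional network whose latent code is regularized by a variational
    information bottleneck (VIB), seeded training with analytic gradients,
    character decoding by row/column score accumulation, and a beta-sweep
    harness demonstrating how the bottleneck weight controls the flow of
    label-irrelevant information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'speller.R'
    'container.R'
    'synthetic.R'
    'preprocess.R'
    'model.R'
    'train.R'
    'cli.R'
    'p300vib-package.R'
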