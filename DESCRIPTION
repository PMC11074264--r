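Package: fuzzyEEG
Title: Convolutional Fuzzy Neural Networks for EEG Emotion Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Binary valence and arousal decoding from multichannel EEG with a
    convolutional fuzzy neural network (CFNN). Provides containers and readers
    for trial-structured EEG recordings with affective self-ratings, a
    windowed-FFT band-power feature extractor over the canonical theta to
    gamma bands, differentiable Gaussian fuzzification and centre-of-gravity
    defuzzification layers, a compact 1-D convolutional network that embeds
    them, with exact per-layer parameter accounting, and stratified hold-out
    and k-fold evaluation with binomial confidence intervals. A seedable
    synthetic-EEG generator with class-dependent band power makes the whole
    pipeline testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
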