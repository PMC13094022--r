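Package: ecogdecode
Title: Semantic Decoding of Intracranial EEG from Time-Frequency Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for decoding a binary stimulus category
    (e.g. animate versus inanimate) from epoched electrocorticography
    recordings. Implements Morlet wavelet power and phase extraction with
    decibel baseline normalization, canonical preprocessing (baseline
    correction, common average referencing, boxcar downsampling,
    extreme-trial rejection, repetition averaging), LASSO-regularized
    logistic classifiers with nested stratified cross-validation, temporal
    generalization matrices, band-wise decoding comparisons, FDR-corrected
    group inference, cosine-distance clustering of generalization profiles,
    BIC-selected piecewise-linear breakpoint analysis of generalization
    width, and per-electrode code-direction maps. Ships a synthetic-data
    generator that plants known band-limited class codes (including
    dynamic sign-flipping codes and early-strong/fast-decay versus
    late-weak/persistent high-gamma envelopes) so that every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
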