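Package: ccaerp
Title: Canonical Correlation Based Decoding of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial filtering and decoding of event-related potentials
    (ERPs) such as the P300, the N2pc and error-related potentials, for
    brain-computer interface research. Canonical correlation analysis
    between concatenated multichannel epochs and model signals (impulse or
    average templates, with optional target/nontarget contrast) yields
    data-driven spatial filters; correlation-based and canonical-variate
    feature spaces feed four built-in classifiers (maximum correlation,
    shrinkage LDA, linear SVM, naive Bayes) for sequence-level intention
    decoding (spellers) and binary single-trial decoding. Includes
    activation-pattern (forward model) reconstruction, cross-validation
    and repetition-curve utilities, conventional preprocessing helpers,
    and seeded synthetic ERP generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
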