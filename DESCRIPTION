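Package: harshift
Title: Activity Recognition Pipelines Under Location and Person Domain Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying smartphone-based human activity recognition when
    the training and deployment data differ in sensor placement (on-body phone
    location) or in the person wearing the device. Provides a synthetic
    multichannel inertial-sensor session generator with configurable domain
    shifts, signal preprocessing (decimation, IIR filtering, virtual sensor
    streams), time- and frequency-domain feature extraction, greedy re-ordering
    of shuffled five-second windows by boundary matching, mutual-information /
    correlation / greedy-wrapper feature selection with quarter-fold domain
    adaptation, Hidden-Markov-Model temporal smoothing of classifier label
    sequences, self-training semi-supervised learning with HMM-aware instance
    selection strategies, phone-location detection, person clustering, and two
    end-to-end hierarchical (general + vehicle) classification pipelines with
    macro-F1 evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
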