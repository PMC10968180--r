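Package: adaptlda
Title: Adaptive Linear Discriminant Analysis for EEG Brain-Computer
    Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for binary electroencephalography (EEG)
    brain-computer interface decoding with a linear discriminant
    analysis (LDA) classifier that adapts to non-stationary signals.
    Provides a synthetic two-class EEG generator with controllable
    class-mean, covariance and class-asymmetric drift; a power
    spectral density feature-extraction chain (notch filter, common
    average reference, sliding-window log band power); static LDA
    training with trial-level cross-validation; incremental updates
    of the class means and of the common inverse covariance matrix
    via update coefficients and the Woodbury identity; a replay
    simulator for offline-train / online-control experiments
    (predicted accuracy, classifier bias, battery-style feedback
    dynamics); and a grid search over candidate update-coefficient
    pairs with selection by modulated accuracy, consistency and bias
    criteria. Results are returned as tibbles with broom-style
    tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
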