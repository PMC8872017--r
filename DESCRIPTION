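Package: nasga
Title: Genetic-Algorithm Neural Architecture Search for Early Sepsis
    Onset Prediction from ICU Time Series
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evolves recurrent-cell architectures with a genetic algorithm
    (DAG-encoded genotypes, weight sharing across child networks, elitism,
    capped roulette selection, per-property crossover, single-gene mutation)
    to predict sepsis onset 0-12 hours ahead from 5-hour windows of hourly
    ICU time series. Includes the full data pipeline: SIRS-based onset
    labeling, event-table harmonization, sliding-window episode extraction,
    Gaussian-process imputation, autoencoder denoising, class balancing,
    AUROC evaluation with bootstrap confidence intervals, and a synthetic
    MIMIC-like event-table generator with a planted pre-sepsis signal so the
    method is exercisable end to end without restricted data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
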