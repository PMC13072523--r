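Package: rimeda
Title: Influence-Matrix Stratification of the Re-Identification Risk of
    Medical Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and stratifies the re-identification
    (deanonymisation) risk of a medical dataset with a weighted
    cross-impact (influence-matrix) system over 13 risk entities grouped
    into four perspectives: data, knowledge, attacker, and
    technical/organisational. From a data controller's per-entity
    weighting it derives active and passive sums, Q-values, factor
    categories, a total risk score with achievable bounds, risk-band
    stratification, lever and countermeasure rankings, sensitivity
    sweeps over the admissible weight space, and the standard evaluation
    charts (score gauge, Q-value chart, active/passive system grid).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
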