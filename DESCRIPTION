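Package: dosegain
Title: Dosimetric Gain Analysis of Paired Radiotherapy Plans via Mean
    Absolute Dose Deviation Penalty Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare paired radiotherapy treatment plans (e.g. prone
    free-breathing versus supine breath-hold whole-breast irradiation) from
    exported dose-volume histograms. Computes the mean absolute dose
    deviation (MADD) of each structure against its reference dose, rolls the
    per-structure deviations into priority-weighted plan penalty scores,
    assesses the per-patient dosimetric gain with paired t-tests and exact
    binomial (Clopper-Pearson) confidence intervals, and screens patient
    characteristics as predictors of the gain with Huber robust linear
    regression, fractional-polynomial nonlinearity checks and
    which-setup-is-better cutoff extraction. A calibrated synthetic-cohort
    generator produces paired voxel-level dose samples and correlated
    patient characteristics so that the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
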