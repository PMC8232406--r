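Package: metaflex
Title: Whole-Body Metabolic Phenotyping from Indirect Calorimetry Cage Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for murine whole-body metabolic phenotyping from
    indirect-calorimetry (CLAMS-style) cage recordings: per-interval respiratory
    exchange ratio, Lusk calorific value, energy expenditure and substrate
    oxidation rates; diurnal binning, hourly moving averages, AUC and
    active/inactive phase deltas quantifying metabolic flexibility; beam-break
    physical-activity quantification and ambulation distance; terminal muscle
    function and fiber histomorphometry summaries; and the study-level
    statistical plan (one-way, repeated-measures and two-way ANOVA, Tukey HSD,
    chi-squared distribution comparisons). Includes a seedable synthetic
    circadian cage-data generator so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    withr,
    car,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
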