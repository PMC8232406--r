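# metaflex

Whole-body metabolic phenotyping of mice from indirect-calorimetry cage data.

Volumetric muscle loss (VML) — the traumatic or surgical removal of a muscle
volume beyond what the body can regenerate — is suspected to carry chronic
*metabolic* comorbidities that outlast the obvious loss of strength. Testing
that idea requires quantifying whole-body metabolism and physical activity of
injured animals in metabolic cages, and terminal muscle outcomes at
sacrifice. `metaflex` implements that analysis end to end for researchers
working with CLAMS-style indirect calorimetry:

* **Per-interval metabolic metrics** — respiratory exchange ratio
  (RER = VCO₂/VO₂), Lusk calorific value (CV = 3.815 + 1.232·RER, kcal/L O₂),
  energy expenditure (EE = CV·VO₂), and the substrate-oxidation pair
  (carbohydrate = 4.585·VCO₂ − 3.226·VO₂; lipid = 1.695·VO₂ − 1.701·VCO₂),
  plus the exact inversion of the oxidation system used as a consistency
  check.
* **Diurnal flexibility statistics** — light/dark phase assignment, binning
  at 24/12/6/1 h, hourly trailing moving averages, trapezoidal AUC, and the
  active-minus-inactive deltas that quantify metabolic rate flux (ΔEE) and
  metabolic flexibility (ΔRER).
* **Physical activity** — beam-break classification (total vs ambulatory
  counts), and ambulation distance at the 1.27 cm X/Y beam spacing.
* **Terminal outcomes** — contractile-table arithmetic (percent change,
  twitch:tetanus ratio, body-mass-normalized torque) and fiber
  histomorphometry (CSA filtering to 50–7,500 µm², fiber-type composition,
  capillarity, regional vs whole-muscle pooling).
* **The study statistics** — one-way, repeated-measures and two-way (Type-II)
  ANOVA, Tukey HSD, and chi-squared histogram comparisons at the
  multiplicity-corrected α = 0.0167, all returning tidy-able result objects.
* **A seedable synthetic cage generator** whose defaults encode the published
  study conditions (24-h EE ≈ 19 kcal/kg/hr with a 4.5 phase delta, RER
  0.93 active / 0.87 inactive, 1.3 km daily ambulation; a 10% EE and 4% RER
  decline six weeks after VML), so the entire pipeline is testable with no
  data download.

Everything is data-frame first and pipe friendly: traces and results are
tibbles, fitted tests have `tidy()`/`glance()` methods, and plot helpers
return ggplots.

## Worked example

Simulate one healthy subject-day, derive the metabolic series, and summarize
flexibility and activity:

```r
library(metaflex)

presets <- builtin_presets()
trace   <- generate_calorimetry_trace(presets$baseline, seed = 7, subject_id = "m01")
series  <- derive_metabolic_series(trace)
series
#> # A tibble: 360 × 9
#>   subject_id group    timepoint timestamp             rer    cv    ee carb_ox
#> 1 m01        baseline pre       2021-06-21 06:00:00 0.908  4.93  23.6    4.48
#> 2 m01        baseline pre       2021-06-21 06:04:00 0.825  4.83  19.4    2.23
#> ...

flexibility_metrics(series)[, 1:7]
#>   subject_id    group timepoint delta_ee delta_rer auc_ee_24h auc_rer_24h
#> 1        m01 baseline       pre     3.79   0.06538      442.1       20.69

activity <- generate_activity_trace(presets$baseline, seed = 7, subject_id = "m01")
summarize_activity(activity)[, c("distance_km", "distance_km_active", "ambulatory_counts")]
#>   distance_km distance_km_active ambulatory_counts
#> 1       1.306              1.007            102819
```

This animal spent 4.5 kcal/kg/hr more energy per hour awake than asleep on
average in the latent model; the single noisy day realizes a ΔEE of 3.79 with
a ΔRER of 0.065, and it walked 1.31 km, 1.01 km of it during the dark phase —
all consistent with the healthy-baseline calibration.

A full longitudinal study (12 subjects recorded before and 2 and 6 weeks
after VML) is one call:

```r
res <- run_study(study_config(design = longitudinal_vml_design(n = 12, seed = 42)))

dplyr::filter(res$cohort_summary, metric %in% c("ee_24h", "rer_24h"))
#>   group timepoint metric    mean      sd     n
#> 1 vml   2wk       ee_24h  18.9   0.153      12
#> 2 vml   2wk       rer_24h  0.893 0.00360    12
#> 3 vml   6wk       ee_24h  17.2   0.248      12
#> 4 vml   6wk       rer_24h  0.864 0.00311    12
#> 5 vml   pre       ee_24h  18.9   0.280      12
#> 6 vml   pre       rer_24h  0.901 0.00457    12

dplyr::filter(res$stats, metric == "ee_24h")
#>   metric test                    statistic   df1   df2  p_value significant
#> 1 ee_24h repeated_measures_anova      243.     2    22 1.00e-15 TRUE
```

The 6-week cohort sits ~10% below pre-injury metabolic rate (17.2 vs 18.9
kcal/kg/hr) with RER down ~4% (0.864 vs 0.901) — the injury's whole-body
metabolic signature — and the repeated-measures ANOVA across timepoints is
decisive. With `out_dir` set, `run_study()` writes the per-subject tables,
cohort summaries, statistics and a manifest as deterministic CSV/JSON.

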