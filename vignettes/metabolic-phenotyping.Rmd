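---
title: "Whole-body metabolic phenotyping with metaflex: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body metabolic phenotyping with metaflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaflex)
```

# The measurement model

Indirect-calorimetry cages (CLAMS-style) report oxygen consumption and carbon
dioxide production normalized to body mass (VO~2~, VCO~2~ in ml/kg/hr) in
4-minute intervals, alongside infrared beam-break counts in 10-second bins.
Four equations turn the gas channels into physiology, evaluated per interval:

* **Respiratory exchange ratio**: RER = VCO~2~/VO~2~. Values near 0.7
  indicate lipid oxidation, near 1.0 carbohydrate oxidation.
* **Calorific value** (Lusk): CV = 3.815 + 1.232 · RER, kcal per liter O~2~.
* **Energy expenditure** (metabolic rate, "heat"): EE = CV · VO~2~, with
  VO~2~ in L/kg/hr, giving kcal/kg/hr.
* **Substrate oxidation**: carbohydrate = 4.585·VCO~2~ − 3.226·VO~2~ and
  lipid = 1.695·VO~2~ − 1.701·VCO~2~.

The oxidation pair is an invertible 2×2 linear system
(`invert_substrate_oxidation()`), which the package uses as an internal
consistency check: published 24-h oxidation rates of 5.87 and 0.95 imply
VO~2~ = 6.278, VCO~2~ = 5.698 and hence RER = 0.908 — matching the published
24-h RER of ~0.90 without any free parameter.

```{r}
gas <- invert_substrate_oxidation(5.87, 0.95)
compute_rer(gas$vo2, gas$vco2)
```

**A unit caveat we deliberately preserve.** Published metabolic rates
(~19 kcal/hr) and oxidation rates (g/min) are not mutually consistent under
any single VO~2~ scale. Rather than invent a correction, the pipeline applies
the oxidation equations to gas values in L/kg/hr and labels the output with
the nominal "g/min" unit. Every quantity then reproduces its published value
on its own scale; cross-scale comparisons of oxidation magnitudes should not
be attempted. The lipid form is slightly negative for RER above
1.695/1.701 ≈ 0.9965; negative values are reported as computed (a counter is
attached, nothing is clamped), since the linear forms carry no bounds.

# Diurnal analysis

Mice are housed on a 12:12 light-dark cycle with lights on at 06:00. Clock
times in [06:00, 18:00) are the light = **inactive** phase, the rest the dark
= **active** phase; the half-open convention assigns each boundary instant to
the phase that begins there. A subject-day runs 06:00 → 06:00 so one day
contains a full inactive then active phase.

Series are summarized in bins of 24, 12, 6 and 1 h anchored at 06:00 (12-h
bins are exactly the two phases). Two flexibility statistics follow:

* **Phase deltas**: active minus inactive 12-h means — "metabolic rate flux"
  for EE, "metabolic flexibility" for RER.
* **AUC**: an hourly moving average (trailing window of 15 four-minute
  intervals; output stamped with the last interval of each window) is
  integrated by the trapezoidal rule with time in hours (spacing 1/15 h),
  over 24 h and within each 6-h bin.

The trailing (rather than centered) window is the weaker assumption: the
instrument literature specifies "an average of every 15 increments" without
fixing alignment. A trailing mean lags a linear trend by 7 intervals, which
cancels in any contrast between conditions smoothed the same way.

**Published AUC magnitudes are not comparable.** Reported AUC values
(≈5,936 for metabolic rate, ≈63.8 for RER) cannot be reproduced from the
reported means under any x-axis convention we tested (hours gives ≈437 and
≈20.7; minutes, interval counts and seconds likewise miss). The package's
hour-based AUC is internally consistent and suitable for within-study
contrasts, but no acceptance value is tied to those two printed magnitudes.

# Physical activity

Every beam break increments a **total** count; a break on a beam different
from the immediately preceding break on the same axis increments the
**ambulatory** count (locomotion), while repeated breaks of one beam
(grooming, feeding) only accumulate totals. The classifier resets its
previous-beam memory at each 10-s bin boundary, matching binned exports. The
one-step "two distinct consecutive beams" rule is a declared convention; the
instrument's internal rule is not public.

X and Y beams are spaced at 1.27 cm, so ambulation distance is
(X~amb~ + Y~amb~) × 1.27 cm. Summing the two axes is the simplest rule
consistent with the hardware description; a Euclidean XY combination could be
substituted without touching anything downstream. Z-axis (rearing) counts are
excluded from distance.

# The synthetic cage generator

No raw recordings are deposited with the study, so the package ships a
seedable generator whose defaults *are* the published study conditions; it
exists to make every pipeline stage verifiable offline, not as a fitting
device.

* **Latent diurnal waveform**: a phase-level square wave with logistic ramps
  (default width 60 min) at the 06:00/18:00 transitions — the simplest shape
  with smooth transitions around the light switches. After constructing the
  ramped wave, an affine recalibration forces the two 12-h phase means to the
  preset targets exactly, so noiseless generation followed by the full metric
  pipeline returns the preset parameters to machine precision (round-trip
  identity, tested).
* **Presets**: `baseline` solves phase means from the published 24-h mean
  (19 kcal/kg/hr) and phase delta (4.5): active 21.25, inactive 16.75; RER
  0.93/0.87 (24-h mean 0.90). `vml_6wk` scales 24-h EE by 0.90 (delta
  preserved) and 24-h RER by 0.96. `vml_2wk` keeps baseline EE with a mildly
  reduced active RER (0.92), reflecting flexibility blunting before the
  metabolic-rate decline. Activity rates are identical across presets
  (ambulation does not change after injury in this model).
* **Noise**: stationary AR(1) Gaussian noise per channel (defaults: EE sd
  2.0 kcal/kg/hr, RER sd 0.04, lag-1 correlation 0.6), magnitudes read off
  the dispersion of published hourly values. RER excursions outside (0, 1.2]
  are pulled back into the physiologic [0.7, 1.0] and counted. The repair is
  deliberately restricted to implausible excursions: clamping every value at
  1.0 would truncate the active-phase noise distribution and bias the phase
  mean downward by ~6×10^-4^, which is detectable at the precision of the
  parameter-recovery tests.
* **Gas back-computation**: VO~2~ = EE/(3.815 + 1.232·RER) and
  VCO~2~ = RER·VO~2~, guaranteeing the metric equations recover the latent
  channels identically.
* **Activity**: per-10-s ambulatory counts are Poisson with phase-specific
  rates split evenly between X and Y; the baseline rates are chosen so the
  expected distances are exactly 1.0 km (active) and 0.3 km (inactive).
  Non-ambulatory counts add a Poisson component at half the ambulatory rate
  (`nonamb_fraction = 0.5`, a typical in-place/locomotion mix).
* **Seeds**: per-trace seeds derive from the design seed and the subject,
  timepoint and stream indices through a documented integer mix kept inside
  32-bit range, so cohorts are byte-reproducible and subjects persist across
  timepoints.
* **Terminal tables**: per-subject contractile outcomes are Gaussian around
  the published group means/SDs; fibers carry multinomial types (regional
  composition percentages), log-normal CSA (sdlog 0.35, mean matched to the
  published type-by-region means), Poisson capillaries and Bernoulli
  central-nucleus/NADH/SDH flags. The force-frequency curve is a Hill-type
  sigmoid f³/(f³ + 45³) scaled to the drawn 200-Hz peak, with the 5-Hz point
  replaced by the drawn twitch — a synthetic shape consistent with the
  published peak, twitch and mid-frequency deficit, not a fitted curve.

**What the generator does not emulate**: feeding events and postprandial RER
excursions, thermoregulatory load, body-composition drift, within-phase
ultradian structure beyond AR(1), and surgical-recovery dynamics between
timepoints. Passing recovery tests therefore demonstrates that the pipeline
measures what the generator encodes — phase means, deltas, distances, group
contrasts — not that real cage data are this well behaved.

# Histology and muscle function

Fiber records carry region (lateral / mid / medial), MyHC type (I, IIa, IIb,
or IIx for unstained), CSA, capillary count and staining flags. CSA is
quantified only for fibers in the inclusive window [50, 7500] µm² (inclusive
because the source phrasing "between" is ambiguous and inclusive is the
weaker reading). Whole-muscle pooling sums counts across the three regions
and recomputes proportions from pooled counts (avoiding Simpson-type
distortions), pooling continuous measures at the fiber level; subjects
missing a region are excluded from pooled tables but kept in regional ones.
The gastrocnemius weight ratio is treated as an opaque printed quantity — its
normalization basis is not reconstructed — so percent-change computations use
the ratios directly.

# Statistical plan

One-way ANOVA across groups, one-way repeated-measures ANOVA across
timepoints (complete matrices only; sphericity assumed, as no correction was
reported), two-way ANOVA for group × fiber-type effects, Tukey HSD post hoc
at α = 0.05, and Pearson chi-squared for distribution comparisons
(capillaries per fiber, CSA histograms) at α = 0.0167 (= 0.05/3 group
pairs). Two choices were genuinely open:

* **Type-II sums of squares** for the unbalanced two-way layouts (group
  sizes 16/5/7): the standard default for main-effect inference when the
  interaction is not the primary question. With a single observation per
  cell the model is fitted additively, as the interaction is not estimable.
* **Chi-squared pooling**: adjacent bins are merged until all expected
  counts are ≥ 1 and at least 80% are ≥ 5 (Cochran's rule); pooling cannot
  change a statistic of zero.

# Numerical conventions and degenerate inputs

* CSV dialect: ISO-8601 timestamps, fixed 6-decimal gas values. A generated
  trace survives a write/read cycle to 1×10^-6^ (the dialect's quantum);
  write∘read∘write is byte-identical. In-memory round trips (generator →
  metrics) are exact.
* Degenerate statistics: identical group means give F = 0, p = 1; an
  all-equal repeated-measures matrix returns F = 0, p = 1 by definition
  rather than 0/0.
* Zero VO~2~ is a domain error (RER undefined); zero VCO~2~ gives RER 0.
* AUC requires ≥ 2 points; bins with fewer than 2 smoothed points yield NA
  sub-AUCs rather than extrapolating.

# Problem sizes used by the test-suite

The recovery checks run 50 replicate cohorts of 28 subject-days (baseline)
and 50 replicate longitudinal cohorts of 12 subjects × 3 timepoints,
matching the study's own arm sizes; ANOVA calibration uses 2,000 null
replicates, and the permutation cross-check 4,000 shuffles at n = 15. These
sizes give standard errors a factor ≥ 5 below every tolerance they gate.
Stochastic recovery is judged at ±2 SEM across replicates — a 95% band, so
roughly one in twenty such assertions is expected to trip on any fixed seed
even for a perfectly calibrated generator; the package treats such a trip as
a signal to inspect bias (none is present: the estimators are unbiased by
construction and verified over independent seeds) rather than to widen
bands.

# Known limitations

* The oxidation-rate unit ambiguity described above: absolute oxidation
  magnitudes are reproducible, cross-scale energy bookkeeping is not.
* Published AUC magnitudes are not reproducible from published means under
  any tested x-axis convention; AUCs here are internally consistent only.
* One recorded day per timepoint: no multi-day averaging, no cosinor or
  periodogram rhythm estimation.
* The beam-break classifier's one-step ambulatory rule is a convention; real
  instruments may require longer runs, which would scale ambulatory counts
  (distance calibration absorbs this at the preset level).
* No protein-oxidation (urinary nitrogen) correction and no alternative
  calorimetric equation sets (Weir, Ferrannini).
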