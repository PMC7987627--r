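# dosegain

Dosimetric gain analysis of paired radiotherapy plans via mean absolute
dose deviation (MADD) penalty scores.

## What problem this solves

For left-sided whole-breast radiotherapy, a prone free-breathing setup and
a supine breath-hold setup trade organ doses against each other: prone
usually spares the ipsilateral lung dramatically but raises the heart and
contralateral-breast dose. Selecting the better setup per patient normally
requires two CT simulations and two complete plans. `dosegain` is for
medical physicists and biostatisticians who have paired dose–volume
histograms (DVHs) for a cohort and want to (a) condense each plan into one
defensible number, (b) quantify how often switching setup helps, and
(c) screen pre-treatment characteristics that predict the benefit — so that
future patients can be triaged without dual planning.

## The metric and the analysis

**MADD.** For a structure with cumulative DVH (D, V), volume V₀ and
reference dose A,

    M = ∫₀^V₀ |D − A| / V₀ dV  ≈  Σⱼ |Dⱼ − A| · δVⱼ / V₀,

with A = 0 for organs at risk (M is then the mean dose) and A = the
prescription for targets. The discrete form uses left-anchored rectangular
strips, δVⱼ = Vⱼ − Vⱼ₊₁, with the terminal point keeping its remaining
volume. All doses are carried in percent of the prescribed dose.

**Penalty score.** A plan is summarized as `Penalty = Σ wᵢ Mᵢ` with
`Σ wᵢ = 1`, a convex combination that stays on the %dose scale. Five
built-in priority types (`type1`, `heart`, `lungs`, `ptvs`, `body`) encode
different clinical emphases.

**Gain analysis.** Per patient, Δ = prone − supine; a gain is Δ < 0
(ties count as no gain). The cohort is assessed by a paired t-test, by the
gain proportion with its exact (Clopper–Pearson) binomial interval, by
subgroup splits at a supine-penalty threshold (Fisher test between
subgroups), and by bullet-arrow chart records.

**Predictor screening.** Each characteristic is fit alone against Δ by
Huber robust regression (`MASS::rlm`, k = 1.345); significance is
|coef/SD| > 1.96; a one-power fractional-polynomial closed test flags
nonlinearity; and the fitted line's zero crossing −intercept/coefficient is
the cutoff where the predicted gain changes sign (e.g. "prone better above
38 mm supine breast depth").

A calibrated synthetic-cohort generator (voxel dose mixtures rolled up to
DVHs, characteristics with a planted pendulousness-to-gain link) makes the
whole pipeline testable without clinical data.

## Worked example

```r
library(dosegain)

cohort <- generate_cohort(cohort_config(n_patients = 116, seed = 1))
report <- run_pipeline(cohort$dvh, cohort$characteristics,
                       weight_sets = c("type1", "heart", "lungs", "ptvs", "body"),
                       split_at = 2, fp = FALSE)
report
#> <dosegain_report>
#>   type1  gain 64/116 (55.2%, 95% CI 45.7-64.4%)
#>   heart  gain 17/116 (14.7%, 95% CI 8.8-22.4%)
#>   lungs  gain 115/116 (99.1%, 95% CI 95.3-100.0%)
#>   ptvs   gain 46/116 (39.7%, 95% CI 30.7-49.2%)
#>   body   gain 105/116 (90.5%, 95% CI 83.7-95.2%)
#>   subgroup split p = 0.000483
#>   predictor screen: 21 characteristics, 4 significant
```

Reading this: on the synthetic cohort, switching to prone reduces the
type-1 (heart-weighted general practice) penalty for 64 of 116 patients;
under a lung-sparing priority prone wins almost always, under a
heart-protection priority it rarely does. The subgroup p-value says the
gain rate depends strongly on the baseline supine penalty.

```r
render_table4(report$penalties)[, c("weight_set", "supine", "prone", "delta")]
#>   weight_set          supine           prone             delta
#> 1       body 3.26(2.21–4.85) 2.51(1.83–3.50) -0.78(-2.77–0.57)
#> 2      heart 2.22(1.52–3.26) 2.82(1.76–4.43)  0.56(-1.02–2.57)
#> 3      lungs 3.53(2.16–6.89) 1.80(1.37–3.08) -1.70(-5.04–0.10)
#> 4       ptvs 2.51(2.20–3.09) 2.60(2.26–3.05)  0.06(-0.57–0.63)
#> 5      type1 2.49(1.80–3.75) 2.37(1.70–3.38) -0.11(-1.74–1.33)
```

Median (range) penalty scores per priority type, in % of prescribed dose.
Among the significant predictors the screen returns, the post-dosimetry
rows read directly as triage rules — e.g. `Supine penalty score`,
coefficient −1.06 (SD 0.089), cutoff 2.4 %dose, `greater_better`: a patient
whose supine plan already scores above ≈2.4 will likely do better prone.

For published cohort estimates the same machinery reproduces the reported
decision bounds:

```r
exact_binomial_ci(72, 116)          # 0.621, CI 0.526–0.709
extract_cutoff(0.278, -0.0073)      # prone better above 38 (mm supine depth)
```

`plot_bullet_arrow(report$pairs)` and `plot_madd_box(compute_madds(cohort$dvh))`
draw the two standard charts. A thin CLI (`exec/dosegain`) wraps
`simulate` and `report` for shell use.

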