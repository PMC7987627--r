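---
title: "Methods: MADD penalty scores and dosimetric-gain analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MADD penalty scores and dosimetric-gain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

When a left-breast cancer patient can be irradiated either supine (with deep
inspiration breath-hold) or prone (free breathing), the two setups trade
organ doses against each other: prone usually spares the ipsilateral lung
dramatically but tends to raise the heart and contralateral-breast dose.
Deciding per patient requires comparing two complete treatment plans, i.e.
two sets of dose–volume histograms (DVHs) over many structures. `dosegain`
implements a pipeline that condenses each plan into a single number, compares
the paired numbers across a cohort, and screens pre-treatment patient
characteristics for their ability to predict which setup will win.

## Mean absolute dose deviation

For a structure with cumulative DVH $(D, V)$, total volume $V_0$ and
reference dose $A$, the mean absolute dose deviation is

$$M = \int_0^{V_0} \frac{|D - A|}{V_0}\, dV,$$

the area between the DVH curve and the reference, read as a volume-weighted
mean deviation. $A = 0$ for an organ at risk — any dose is unwanted, and $M$
reduces to the mean dose — and $A$ equals the prescription for a target
volume, where deviation in either direction (cold or hot) is penalized. On
$n$ tabulated DVH points the integral is evaluated by left-anchored
rectangular strips,

$$M = \sum_{j=1}^{n} \frac{|D_j - A|\,\delta V_j}{V_0},
\qquad \delta V_j = V_j - V_{j+1},\; \delta V_n = V_n,$$

exactly as `madd()` computes it. Design choices worth knowing:

* **Rectangles, not trapezoids.** The strip sum is exact for the
  step-function DVHs that planning systems export and carries an $O(h)$ bias
  for a smoothed curve on a grid of width $h$. All internal grids default to
  $h = 0.1$% of the prescribed dose, so the bias is below one grid width —
  the property the test suite asserts against a voxel-level oracle.
* **Terminal strip.** The last point keeps its full remaining volume at its
  own dose; the curve is never extrapolated beyond the tabulated maximum.
* **Canonicalization.** Exports sometimes repeat a dose; duplicates are
  merged keeping the smaller cumulative volume (the right-continuous
  step-function value). A curve whose first volume falls short of the
  declared total (a truncated export) gets $(0, V_0)$ prepended, since by
  definition the whole structure receives at least zero dose.
* **Units.** All pipeline math runs in percent of the prescribed dose;
  `read_dvh()` converts Gy exports at ingestion. The MADD is invariant to the
  volume unit (mL or fraction) because $\delta V / V_0$ is unitless.

## Penalty scores and priority types

A plan's penalty is the convex combination
$\mathrm{Penalty} = \sum_i w_i M_i$ with $\sum_i w_i = 1$, so it stays on the
percent-dose scale and reads as a weighted average dose deviation. Five
built-in priority types express clinical emphases (heart-first practice,
cardiac comorbidity, pulmonary risk, target coverage, whole-body low dose).
Only the `body` type weights the external contour; elsewhere its weight is
zero because the body envelope contains the organs and targets and would
double-count them. A missing contour for a positively weighted structure is
an error by default; `renormalize_missing = TRUE` rescales the remaining
weights and warns, because real exports do lose contours. Scores are carried
at full precision and rounded to two decimals only in `render_table4()`.

## Gain assessment

The per-patient difference $\Delta = \mathrm{prone} - \mathrm{supine}$
defines a *gain* as $\Delta < 0$. Ties count as no gain — the conservative
choice toward prone, made explicit because exported scores can coincide.
Three complementary views:

1. `paired_t()`: the aggregate paired t-test on $\Delta$.
2. `count_gains()`: the gain count with its Clopper–Pearson interval,
   computed from Beta quantiles
   ($\mathrm{qbeta}(\alpha/2; k, n-k+1)$, $\mathrm{qbeta}(1-\alpha/2; k+1,
   n-k)$) with the boundary conventions $\mathrm{low}=0$ at $k=0$ and
   $\mathrm{high}=1$ at $k=n$. The test suite checks it against
   `binom.test()` and verifies, by enumerating the binomial support, that
   exact coverage at $n=116$, $p=0.6$ is at least nominal.
3. `bullet_arrow()`: patients sorted by supine penalty, arrows to the prone
   penalty — the chart that makes the baseline dependence visible.

`split_gains()` contrasts the gain rate above and below a supine-penalty
threshold (default 2% of prescribed dose). The two-proportion comparison
uses Fisher's exact test by default, with the continuity-corrected
chi-square as an option; published analyses of this kind rarely state the
method, and on the published subgroup counts both land far below 0.001, so
the choice is documented rather than consequential. Percentages are reported
rounding half away from zero to one decimal, the convention of clinical
tables (`round_half_up()`).

## Predictor screening

Each characteristic is screened alone against $\Delta$:

* **Robust fit.** `robust_fit()` wraps `MASS::rlm`: Huber M-estimation with
  tuning constant 1.345, scale from the median absolute deviation,
  iteratively reweighted least squares up to 50 iterations with coefficient
  tolerance $10^{-8}$ — the defaults of the implementation the approach was
  built on. The coefficient SD is the standard error from the final IRLS
  weighting. On exactly collinear (noiseless) data the MAD scale collapses
  and IRLS cycles, so the fit falls back to least squares, with which the
  M-estimate coincides there. A characteristic is *significant* when
  $|\hat\beta / \mathrm{SD}| > 1.96$. Complete cases per characteristic; no
  imputation, at least 10 complete cases required.
* **Cutoff.** The fitted line $\Delta(x) = a + b x$ changes sign at
  $x^* = -a/b$: with $b < 0$ larger values favour prone
  (`greater_better`), with $b > 0$ smaller ones do. The cutoff is *not
  identifiable* when $|b/\mathrm{SD}| < 0.5$ (slope indistinguishable from
  zero at half a standard error) or when $x^*$ falls outside the plausible
  range of the characteristic; published tables mark such rows NI without
  stating a rule, and this is the package's operationalization. Cutoffs are
  rounded only at report time (`format_cutoff()`): integers for mm, mL, kg,
  kg/m², cm and years; one decimal for ratios, litres and %dose.
* **Nonlinearity.** `fp_select()` is a one-power fractional polynomial
  (FP1) check: candidate transforms $x^p$, $p \in \{-2, -1, -\tfrac12, 0
  (\log), \tfrac12, 1, 2, 3\}$, Gaussian deviance $n\log(\mathrm{RSS}/n)$,
  and a closed test — best FP1 against the null on 2 df (one for the power
  choice, one for the slope), then best FP1 against the straight line on
  1 df. "Two degrees of freedom" is interpreted as permitting FP1 only;
  two-power FP2 models are out of scope. Non-positive predictors are
  shifted by the standard rule (minus the minimum plus the smallest gap
  between distinct values). The *type-I error* of the procedure is the
  probability of rejecting the null at all when $y$ is independent of $x$;
  simulation (1000 replicates, $n=100$, lognormal predictor) puts it near
  the nominal 0.05, which the acceptance suite asserts as a band of
  [0.03, 0.07]. Declaring the specifically *nonlinear* form is rarer than
  $\alpha$ by construction of the closed sequence.
* **Screen order.** `screen_all()` reports characteristics in a fixed
  clinical grouping (pendulousness, breast/body, tumor location, breast
  size, body size, breath-hold capability, other, then the post-dosimetry
  penalty scores as predictors of $\Delta$), so output ordering is
  deterministic.

## The synthetic cohort generator

No clinical cohort ships with the package, so `generate_cohort()` produces
one with the statistical structure the analysis assumes:

* **Dose model.** Each structure/setup gets a two-component voxel mixture: a
  Binomial share of in-field voxels on a truncated-normal plateau, the rest
  on an exponential low-dose tail; 10,000 voxels per structure keep the DVH
  grid bias on the MADD below 0.1% dose. Defaults are calibrated so
  cohort-mean MADDs land near typical clinical values — ipsilateral lung
  ≈7.6% supine vs ≈1.9% prone, heart ≈1.9% vs ≈3.4%, contralateral breast
  ≈0.8% vs ≈1.7% — and the target breast mean dose stays within the 95–107%
  planning window.
* **The planted link.** Pendulousness (depth ratio, lognormal around 1.9)
  attenuates the prone ipsilateral-lung in-field fraction as
  $(r_{\mathrm{ref}}/r)^{\kappa}$ with $\kappa = 3$, so the
  characteristic-to-gain association flows through MADD and penalty
  computation rather than being pasted onto the scores. Mean-one lognormal
  patient factors (log-sd 0.35 in-field, 0.20 out-of-field), drawn
  independently per setup, create realistic spread and the observed
  negative association between the supine penalty and $\Delta$.
* **Characteristics.** Sampled to mimic published cohort medians and ranges
  (breast volume median ≈484 mL, weight median ≈67 kg, BMI median ≈25, age
  median ≈57.5, couch and tumor-location frequencies), with chart-like
  missingness in weight, height and preference.
* **Direct mode.** `link_mode = "direct"` skips voxel simulation and draws
  $\Delta = 1.244 - 0.795\,r - 0.35\,(s - 2.45) + \varepsilon$,
  $\varepsilon \sim N(0, 0.5)$, against a sampled supine score $s$. The
  planted slope is then exactly known, which is what the
  parameter-recovery studies use (100 replicates at $n=500$ recover it
  within 3 SE in ≥95% of runs, and planting 3 gross outliers of +5% dose
  moves the robust slope by less than 1 SE).
* **Outliers.** `plant_outliers()` emulates the occasional patient whose
  prone plan is much worse despite low pendulousness: $\Delta$ shifted up,
  ratio forced below 1.5, ids recorded in an attribute.

What the generator does **not** emulate: anatomy, beam geometry, or any 3D
dose physics — the mixtures are statistical surrogates; correlations between
structures beyond the planted links; measurement error in the depth
measurements. Passing tests therefore demonstrate that the pipeline
recovers what it assumes from data of this shape, not that clinical cohorts
satisfy those assumptions.

## Validation problem sizes

The shipped suites use deliberately desk-scale problems: 100 random
structures of 10,000 voxels for the MADD oracle, a 116-patient dose-mode
cohort for generator calibration, 100 direct-mode replicates of 500 patients
for slope recovery, and 1000 null replicates of 100 observations for the
FP1 size check. Published cohort-level headline numbers (mean penalties,
the 62.1% overall gain rate, cohort regression coefficients) depend on the
original patients and are not reproducible from synthetic data; what is
reproduced exactly are the quantities whose published inputs are available —
binomial intervals from the printed counts and prone-better cutoffs from the
printed regression estimates (only rows whose printed numbers are
self-consistent; several published cutoffs were evidently computed from
unrounded coefficients, e.g. 0.338/0.0111 = 30.5 printed as ">31").

## Worked pipeline

```{r example}
library(dosegain)

cohort <- generate_cohort(cohort_config(n_patients = 116, seed = 1))
report <- run_pipeline(cohort$dvh, cohort$characteristics,
                       weight_sets = c("type1", "heart", "lungs", "ptvs", "body"),
                       split_at = 2, fp = FALSE)
report
render_table4(report$penalties)
plot_bullet_arrow(report$pairs)
```

## Known limitations

* DVHs are the interface; the package never touches DICOM RT-DOSE voxel data.
* Univariable screening only — no multivariable model and no
  multiple-testing correction across characteristics or weight sets, by
  design of the analysis it implements.
* The NI rule and the Fisher default are the package's interpretations of
  published practice and are documented as such above.
* Weight sets express institutional priorities, not fitted dose–response
  models; changing them changes the verdict, which is the point of the
  priority-type comparison.
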