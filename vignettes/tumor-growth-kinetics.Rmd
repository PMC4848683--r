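---
title: "Deconvolving tumor growth into proliferation and apoptosis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving tumor growth into proliferation and apoptosis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorkinetics)
```

## The scientific problem

In a two-strain rat model of premenopausal obesity and breast cancer,
dietary obesity-sensitive (DS) animals carry a markedly higher mammary
tumor burden than obesity-resistant (DR) animals over the same nine-week
window after carcinogen exposure. The question this package's pipeline
addresses is *kinetic*: is the extra burden explained by faster per-tumor
mass accumulation, and if so, is the acceleration driven by a shorter cell
cycle, by slower clearance of apoptotic cells, or both?

The framing is a tissue-size balance. Writing $\Delta S$ for the rate of
change of tissue size, $n$ for cell number, and $k_P$, $k_D$ for per-cell
proliferation and death rates,

$$\Delta S = n\,(k_P - k_D),$$

homeostasis is $\Delta S = 0$; a growing tumor has $\Delta S > 0$. Each
per-cell rate splits into a pool size and a process duration: the
proliferating pool is the Ki67-immunoreactive fraction $P_n$ cycling with
duration $P_d$, and the dying pool is the apoptotic index $D_n$ whose
morphology persists for duration $D_d$. Two derived estimators follow:

* **Cell-cycle duration** (hours): $P_d = P_n / \text{MI}$, the
  proliferative fraction over the mitotic index
  (`cell_cycle_duration()`).
* **Apoptotic duration** (hours):
  $D_d = D_n \big/ \left( P_n/P_d - \Delta S/n \right)$
  (`apoptotic_duration()`), where $\Delta S$ is the per-tumor necropsy
  mass converted to cells (at $10^{-9}$ g/cell) divided by the hours
  between first palpation and termination, and $n$ is the strain-level
  growth slope converted to cells gained per hour.

Growth slopes come from ordinary least squares of necropsy mass on the
week the tumor was first palpated, counted as *weeks prior to end of
study* (0 = found at termination; larger values = longer growth window).
`fit_mass_on_week()` fits per strain and `compare_slopes()` tests the
strain-by-week interaction in a pooled model.

## Units in the cell-cycle estimator

The duration formula divides a percentage by a mitotic index, and the
result depends on the unit chosen for the index. The default mode
`"as-published"` divides Ki67 percent by mitotic **figures per field**;
with typical values (9% Ki67, 0.45–0.6 figures/field over 700–1000 cells)
this gives 16–21 h, consistent with the ~24 h textbook cycle. The
dimensionally homogeneous alternative, mode `"per-cell"`, divides Ki67
percent by the mitotic **percentage** ($100 \times$ figures/cells) and
gives values near 170 h on the same data — about 8.5-fold larger, the
factor being cells-per-field/100. Both modes are exposed and reported;
analyses comparing groups are unaffected by the choice because it cancels
in ratios and percent differences.

Two further conventions matter and are deliberate:

* **Per-tumor, then average.** Durations are computed per tumor and group
  means are means of per-tumor ratios, not ratios of group means (the two
  differ because the ratio is nonlinear in its inputs).
* **Undefined durations.** If $P_n/P_d \le \Delta S/n$, observed growth
  meets or exceeds proliferative supply under the model and $D_d$ has no
  positive solution; the estimate is returned as `NA` with a count of
  exclusions (never a silent negative). Tumors first palpated at
  termination (week 0) have no elapsed growth window, so their $\Delta S$
  and $D_d$ are likewise flagged undefined.
* **$n$ is a rate.** The balance uses a cell number $n$, but the available
  datum is a growth rate (slope in cells gained/h); the estimator uses the
  rate as written in the source analysis. The ratio $\Delta S / n$ is then
  dimensionless, and $D_d$ inherits the hours unit from $P_d$. This
  dimensional irregularity is inherent to the estimator, not to the
  implementation.

## Per-field count models

Mitotic figures and apoptotic bodies per high-power field are counts with
variance typically exceeding the mean (cells within a field are not
independent). The working family is the gamma-mixed Poisson — negative
binomial with mean $\mu$ and gamma shape $k$, variance
$\mu + \mu^2/k$ — which nests Poisson as $k \to \infty$.

* `fit_poisson()` / `fit_negbin()` give comparable maximum-likelihood
  fits (for this parameterization the ML mean is the sample mean, and $k$
  is profiled by one-dimensional optimization of the log-likelihood in
  $\log k$). When the sample variance does not exceed the mean the $k$
  estimate diverges; `fit_negbin()` returns a flagged Poisson-limit fit
  with the extra-parameter AIC penalty rather than failing.
* `overdispersion_test()` is Fisher's dispersion-index score test,
  $\sum (x-\bar x)^2/\bar x \sim \chi^2_{n-1}$ under Poisson, one-sided
  for overdispersion. Its type-I error is verified at the 5% level by
  simulation in the test suite.
* `compare_groups_nb()` fits a log-link negative-binomial regression with
  a group indicator (Wald test by default, likelihood-ratio optional) and
  reports the per-cell event probability as mean events per field over
  mean cells per field. If the dispersion diverges during fitting the
  comparison falls back to a Poisson GLM, which is the limiting model.

## Ki67 field sampling

`plan_fields()` encodes the image-capture rule: total 400× fields by the
section's long-axis category — under 10 mm: 5; 10 to under 15 mm: 10;
15 to under 20 mm: 15; 20 mm and above: 20 — with
$\lceil \text{total} \times \text{hotspot\%}/100 \rceil$ fields taken from
intensely stained regions and the remainder from typical regions. The
source categories leave exactly 20 mm unassigned between "under 20" and
"over 20"; the planner assigns it to the 20-field category so coverage of
the axis is monotone and total. Partial hotspot fields always round up.

## Expression normalization and the multivariate stage

Blot or capillary signals are consumed as extracted numbers (densities or
peak areas) and expressed relative to the GAPDH loading control
(`normalize_to_loading_control()`), making them invariant to common gain;
`phospho_total_ratio()` derives the phospho-Rb/total-Rb checkpoint index,
and `table1_ratio_report()` turns per-depot adiposity means into folds and
percent differences.

The multivariate stage is implemented in-package in the chemometrics
style, because its exact conventions (scaling, deflation, sign, and the
cross-validation scheme) determine the numbers:

* `pca_fit()` — NIPALS components on mean-centered, unit-variance scaled
  data; per-component $R^2X$ is the explained fraction of total scaled
  sum of squares. Loadings are unit-norm with the largest-magnitude
  element oriented positive, so results are reproducible; tests verify
  agreement with a singular-value-decomposition oracle to $10^{-6}$.
* `q2_crossval()` — row-wise cross-validation in contiguous folds; each
  held-out element is predicted from the held-out row's *other* variables
  (the score on the training loading is recomputed leaving the target
  variable out), so no element predicts itself. $Q^2_a = 1 -
  \mathrm{PRESS}_a/\mathrm{SS}_{a-1}$. Rank-deficient noiseless structure
  gives $Q^2 \approx 1$; pure noise gives $Q^2 \le 0$ on average. The
  element-wise scheme of the commercial tool this emulates is proprietary,
  so published $Q^2$ values from that tool are data- and scheme-dependent
  and are not reproduction targets.
* `hotelling_two_group()` — two-sample Hotelling $T^2$ with pooled
  covariance and the exact $F$ reference; in one dimension it equals the
  squared pooled $t$ statistic, which the tests assert to $10^{-10}$.
* `pls1_fit()` — single-component PLS1; on scaled data the weight vector
  is proportional to $X^\top y$, and coefficients are reported on the
  scaled scale so magnitudes are comparable across the 29 predictors.

## What the synthetic generator emulates

`cohort_config()` defaults describe the study conditions: 103 DR and 101
DS rats; incidences 0.65 and 0.91; mean multiplicities 2.14 and 2.82 per
tumor-bearing rat (truncated Poisson — together these reproduce the
143/259 expected carcinoma counts); detection threshold 0.1 g; detection
weeks uniform on 0–4 (the palpation window before the 9-week
termination; the distribution of detection weeks is not constrained by
the published means, so uniform is the neutral choice and is
configurable); growth slopes 0.533 and 0.968 g/week; per-field censuses
of mean 850 cells (clipped to 500–1500); negative-binomial mitotic and
apoptotic means 0.448/0.571 and 1.877/2.616 with shared dispersion
$k = 1.5$ (clearly overdispersed, as the field data were); Ki67 means
9.0/9.4% with between-tumor sd 3; and a 29-variable panel of checkpoint
and apoptosis regulators with DS shifts in the directions the analysis is
designed to detect (XIAP, cleaved caspase 3 and cytochrome c up;
Apaf-1/Bax/p21 down; phospho-Rb ratio up).

**Mass-noise model.** Necropsy mass is
$\text{threshold} + \text{slope} \times \text{week}$ in expectation.
Tumors detected at termination are pinned at the detection threshold
(they have had no post-detection growth), while tumors detected earlier
add homoskedastic Gaussian growth noise (default sd 0.6 g), bounded below
by the threshold. This choice is deliberate: noise truncated at the
threshold *at every week* inflates the expected mass most where the mean
sits at the threshold (week 0), which biases the fitted slope downward by
more than a standard error at realistic noise levels. Pinning week-0
masses keeps the regression essentially unbiased and makes classical OLS
standard errors mildly conservative — simulated two-standard-error
coverage of the true slope is ~98% over 200 cohorts, verified in the
test suite. The cost is that week-0 tumors contribute no residual
variance, which real palpation data would have.

Features of real data the generator does **not** emulate: rat-level
clustering of tumors (tumors are simulated and analyzed as independent,
mirroring the source analysis — a caveat, since multiple tumors share a
host); right-skewed mass distributions at the magnitude implied by the
published slope standard errors (residual sds of 1.2–3.2 g cannot be
combined with a hard detection floor without distorting the slope, so
the default noise is smaller); correlations among panel variables (drawn
independently within strain); spatial structure within sections (hotspot
fields have the same count distribution as typical fields); and any
diet, body-weight or endocrine covariates. Passing tests therefore
demonstrate estimator correctness and calibration under the model's own
assumptions, not robustness to these real-data features.

## Numerical choices

* NIPALS convergence: relative score change below $10^{-12}$ or 5000
  iterations. The tolerance is deliberately tight: the iteration is a
  power method whose convergence rate degrades as component eigenvalues
  approach each other, and looser settings visibly degrade loading
  accuracy on random matrices.
* Negative-binomial profile likelihood is maximized over
  $\log k \in [-12, 15]$, covering extreme under- to over-dispersion.
* Truncated-Poisson multiplicity sampling solves
  $\lambda/(1-e^{-\lambda}) = m$ by root finding, then inverse-CDF
  samples conditioned on $\ge 1$.
* Ki67 draws are bounded to the open interval (0, 100); with the default
  mean and sd the bound is essentially never active.
* Seed policy: one configuration seed fans out to deterministic per-stage
  child seeds, so `generate_field_counts()` is reproducible regardless of
  whether `generate_cohort()` ran first, and the whole pipeline is
  byte-reproducible for fixed seed (asserted in the tests).
* Test and simulation problem sizes: Monte-Carlo calibrations use 200
  cohorts at full study size for slope recovery, $10^5$ draws for count
  moment and likelihood recovery checks, 500–1000 replicates for type-I
  error calibration, and 20 tumors × 10 fields per group for the count
  group-comparison power checks — sizes at which binomial Monte-Carlo
  error is small relative to the asserted bands.

## A worked run

```{r, eval = FALSE}
cfg <- cohort_config(seed = 1)
report <- run_pipeline(cfg, "run1")
report$growth$comparison$ratio      # DS/DR slope fold-change
report$kinetics$percent_difference  # duration contrasts
report$counts$apoptotic$group_test  # NB group comparison
report$multivariate$pls1$top_positive
```

## Known limitations

* Tumors from the same rat are treated as independent in the growth
  regression; a mixed model with rat-level effects is out of scope by
  design but would be the natural extension.
* The apoptotic-duration estimator inherits the identification
  assumptions of the balance model (Ki67 area fraction read as a cell
  fraction; a strain-level growth rate standing in for $n$); its absolute
  values should be read as model-based estimates, while group contrasts
  are more robust.
* The $Q^2$ cross-validation scheme is one of several defensible
  element-wise schemes; absolute $Q^2$ values are scheme-dependent even
  though their qualitative behavior (structure vs. noise) is not.
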