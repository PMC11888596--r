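---
title: "Multi-organ biological aging from clinical biomarkers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ biological aging from clinical biomarkers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgaging)
```

# The scientific problem

People of the same calendar age can age at different rates, and different
organ systems within one person can age at different rates again.
`orgaging` implements a complete two-wave cohort analysis of this
phenomenon: it estimates a *biological age* (BA) — in years — for a
comprehensive 15-marker clinical panel and for five organ systems
(cardiopulmonary, metabolic, liver, renal, immune), validates each BA
against the diseases its organ system should predict, and then asks the
substantive question: **when people change their lifestyle between two
survey waves, does their biological aging change too, and which lifestyle
factor contributes most?**

The package is written so that every stage can be exercised on a seeded
synthetic cohort with known ground truth. The synthetic generator is a
first-class, tested module: it defines the study conditions under which
the estimators are verified to recover truth.

# Biological age: the Klemera–Doubal estimator

For each biomarker $j$ and sex stratum, a linear age trend is fit by
ordinary least squares on the baseline wave:

$$x_j = q_j + k_j \, \mathrm{CA} + \varepsilon_j,
  \qquad \varepsilon_j \sim (0, s_j^2).$$

Each marker then carries an inverse-regression age estimate
$(x_j - q_j)/k_j$, and the uncorrected Klemera–Doubal estimate is their
slope-to-noise weighted average:

$$\mathrm{BA}_E
  = \frac{\sum_j (x_j - q_j)\, k_j / s_j^2}{\sum_j (k_j/s_j)^2}.$$

$\mathrm{BA}_E$ is a convex combination of the per-marker estimates, so
it always lies between their minimum and maximum — a property the test
suite checks on randomized panels. The headline estimator additionally
anchors on chronological age, treated as one more "marker" with variance
$s_{BA}^2$:

$$\mathrm{BA}_{EC}
  = \frac{\sum_j (x_j - q_j)\, k_j / s_j^2 + \mathrm{CA}/s_{BA}^2}
         {\sum_j (k_j/s_j)^2 + 1/s_{BA}^2}.$$

As $s_{BA} \to \infty$ the anchor vanishes and
$\mathrm{BA}_{EC} \to \mathrm{BA}_E$; as $s_{BA} \to 0$ it collapses to
CA. We estimate $s_{BA}^2$ from the training data as the mean squared
deviation of $\mathrm{BA}_E$ from CA minus the dispersion a noise-only
panel would produce,

$$\hat s_{BA}^2 = \overline{(\mathrm{BA}_E - \mathrm{CA})^2}
  \;-\; \frac{1 - r_{char}^2}{r_{char}^2}\cdot
        \frac{(\Delta \mathrm{age})^2}{12\,m},$$

with $m$ the number of markers, $\Delta\mathrm{age}$ the training age
range, and $r_{char}$ the characteristic marker–age correlation (the
weighted mean of $|r_j|$ with weights $|r_j|/\sqrt{1-r_j^2}$). The
estimate is floored at a small positive constant ($10^{-2}$ years$^2$) so
the corrected estimator is always defined. **BA acceleration** is
$\mathrm{BA} - \mathrm{CA}$ at the same time point, in years; positive
values mean faster-than-calendar aging.

Design choices worth knowing:

* *Training wave.* Parameters are fit on baseline records only and both
  waves are scored with that one parameter set, so within-person change
  in acceleration is not contaminated by parameter drift. This is
  exposed as `training_wave` in `score_panels()`.
* *Sex stratification.* All parameters are per-sex; tests verify that
  permuting or corrupting one stratum leaves the other untouched.
* *Anchoring and attenuation.* The CA anchor is a bias–variance
  trade-off: it shrinks noisy accelerations toward zero, which stabilizes
  cross-sectional comparisons but multiplicatively attenuates regression
  coefficients that use acceleration as an outcome. Parameter-recovery
  tests therefore score with `use_ca_anchor = FALSE` (unbiased
  inverse-regression scale), while the pipeline default keeps the anchor.
  Sign patterns and mixture *shares* are invariant to this uniform
  attenuation.
* *No transforms.* Markers enter in their native units; no log or other
  transform is applied by default.
* *Screening.* `screen_biomarkers()` retains markers with missingness
  below 30% and absolute age correlation of at least 0.10 in both sex
  strata with a consistent sign. The correlation threshold is a
  documented stand-in (configurable); the shipped panels can be used
  directly without screening.

# The Healthy Lifestyle Index

Five binary healthy-factor indicators are summed into an HLI of 0–5,
dichotomized at 4–5 = "healthy":

| factor   | healthy when |
|----------|--------------|
| smoking  | never smoker |
| alcohol  | drinks less than once per week |
| diet     | modified aMED at or above the same-wave population median |
| exercise | 1–2/week, 3–5/week, or daily |
| sleep    | 7–8 hours per night (closed interval) |

The diet score is a modified alternate Mediterranean diet (aMED) score
with the alcohol item removed: seven food components, each scored 1–5 by
quintile rank within the reference population (protective components
score high when intake is high; red/processed meat scores high when
intake is low), giving a total of exactly 7–35. Because the per-component
rule is rank-based, the score is invariant to any strictly monotone
transform of a component's intakes, and a degenerate (constant) component
gives everyone the midpoint score of 3 — both tested properties. The
seven-component list ships as `amed_components()` and is configurable;
the median threshold is computed per wave over the pooled analysis
population (per-sex or pooled-across-waves medians are possible
alternatives the package does not default to).

Between-wave change in a single factor is three-valued: *healthier*
(unhealthy at baseline, healthy at follow-up), *unhealthier* (the
reverse), or *unchanged*. HLI change compares scores (continuous) or the
healthy/unfavorable categories (binary). Change categorization is
antisymmetric under swapping the waves, which the suite checks on random
data.

Sensitivity analyses swap one factor's criterion at a time via
`alternative_definitions()`: never-or-former smoking; up to 3
drinks/week; diet in the top 40%; exercise at least 3 times/week; sleep
6–9 hours.

# Disease validation of the biological ages

Validation is cross-sectional on baseline data. Each panel's acceleration
is standardized (z score) and categorized at the ±1 cut (mid = |z| ≤ 1 is
the reference; the cut can be switched to raw years). Logistic
regressions of each mapped disease on the continuous per-SD acceleration
— adjusted for the five lifestyle flags plus demographic covariates —
yield odds ratios with Wald 95% CIs; the cardiopulmonary panel is never
categorized because its anchored accelerations are numerically small. A
panel passes when at least one mapped disease shows OR > 1 with a CI
excluding 1; the renal panel has no mapped disease and is reported as
unvalidatable. No multiple-testing correction is applied, matching the
analysis convention the package implements. Separation or
non-convergence is flagged in the output rather than silently returned.

# Lifestyle change and acceleration change: the fixed-effects model

With two waves, the fixed-effects (within-person) estimator is exactly
the first-difference estimator, and the package implements it that way:

$$\Delta \mathrm{accel}_i = \alpha + \beta^\top \Delta \mathrm{exposure}_i
  + \gamma^\top \Delta Z_i + \delta^\top W_i + u_i,$$

where $Z$ are time-varying covariates (differenced; categorical
covariates are expanded to indicators first) and $W$ are time-invariant
covariates plus baseline age entered as *level* terms. A textbook
fixed-effects model absorbs $W$ entirely; entering levels in the
differenced equation is the one way the stated adjustment can have any
effect (it is equivalent to covariate-by-wave interactions). The
"standard" variant drops the level terms and is the pure within
estimator — the suite verifies the first-difference/within identity to
machine precision. Standard errors are heteroskedasticity-robust (HC1).
Exposures enter either as the five healthy flags jointly, as the
continuous HLI, or as the binary HLI.

Degenerate designs are handled explicitly: an exposure with no
within-person variation is an error (its effect is unidentified); a
covariate that differences to zero is dropped with a warning; covariate
dummies that are structurally collinear (e.g. menopausal categories,
which partition women and never apply to men) or driven by fewer than
three persons are dropped with a message. Short-term linearity of the
change effect is assumed throughout.

Subgroup analyses refit the model within strata (sex, baseline age < 60
vs ≥ 60, ethnicity, urbanicity, baseline acceleration sign, baseline
disease status), excluding the stratified variable from the covariates,
and test heterogeneity with Cochran's Q:

$$Q = \sum_i w_i (\beta_i - \bar\beta_w)^2, \qquad w_i = 1/se_i^2,$$

chi-square with (strata − 1) df under homogeneity, flagged at
$\alpha = 0.1$.

# Quantile G-computation

To apportion the joint lifestyle effect among the five factors, the
package implements linear quantile G-computation **on the same
differenced design as the fixed-effects model**, so both answer the same
estimand. Exposures are quantile-scored (`q = 4` by default); binary
flags and between-wave flag changes (values in {−1, 0, 1}) are already
scores and pass through unchanged, which makes the QGC mixture effect

$$\psi = \sum_f \beta_f$$

*identically* equal to the sum of the joint fixed-effects exposure
coefficients — an equality the suite asserts to $10^{-10}$. Relative
contributions are the coefficients normalized within their sign group,

$$w_f^{-} = \frac{|\beta_f|}{\sum_{g:\,\beta_g<0} |\beta_g|}
  \quad (\beta_f < 0),$$

and symmetrically for the positive group. Negative-direction
(protective) weights are the headline output; positive weights are
reported but flagged separately. The $\psi$ confidence interval comes
from a seeded nonparametric bootstrap over persons (percentile, 200
replicates by default), or a robust Wald interval when
`bootstrap_reps = 0`. Whether such a mixture analysis should use baseline
levels, pooled person-waves, or change scores is genuinely open; the
package commits to change scores for consistency with the fixed-effects
exposures and documents that as an assumption.

# The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws a two-wave panel of `n` adults:

* **Ages 30–79** at baseline (uniform), inter-wave gap Normal(2.0, 0.25)
  years truncated to [1, 3] — the study design it emulates has an
  approximately 2-year gap with no published per-person distribution.
* **Biomarkers** follow $x_j = q_j + k_j(\mathrm{CA} + a) + \varepsilon$
  per sex, where $a$ is the latent acceleration of the marker's organ
  system: per-factor unhealthy penalties plus a shared frailty
  (SD 2 years) and an organ-specific frailty (SD 1.5 years), both
  time-invariant. Marker intercepts, slopes and noise SDs are
  physiologically plausible configuration values, not empirical claims.
* **Lifestyle states** are correlated across factors through a shared
  "health consciousness" propensity (loading 0.8) with marginal healthy
  prevalences of 0.65/0.78/0.50/0.45/0.55 (smoking/alcohol/diet/
  exercise/sleep); wave-1 states follow per-factor transition
  probabilities chosen so that smoking and alcohol change in under 10%
  of people while diet and sleep change in over a third and exercise in
  about 30% — the change-frequency pattern characteristic of repeated
  lifestyle surveys. Raw fields (smoking status, drinking frequency,
  exercise category, sleep hours, seven diet component intakes) are
  drawn consistently with the latent states; diet components are
  separated strongly enough (log-scale shift 1.5) that the median-split
  scored flag agrees with the latent flag for ~99.5% of records.
* **Default effect sizes** are point estimates on the scale the
  published lifestyle-change literature reports (tenths of a year per
  factor; e.g. metabolic smoking 0.54 years, comprehensive diet 0.15
  years; the comprehensive-column values are reused for the renal and
  immune systems, for which no reported scale exists). Their negated sign-group shares are the ground-truth
  mixture weights stored alongside the data.
* **Diseases** are Bernoulli draws from logistic links on baseline organ
  acceleration. Slopes (0.35–0.9 per year) are set so the per-SD odds
  ratios land in the 1.15–1.25 range — the order of magnitude reported
  for clinical-panel biological ages — and are zero for cancer and
  rheumatoid arthritis, so the immune panel genuinely fails validation
  while cardiopulmonary, metabolic and liver pass, reproducing the
  published keep/drop pattern.
* **Ground truth** (latent accelerations, latent flags, effect matrix,
  implied mixture weights) is stored next to the data and never consumed
  by estimation code.

Not emulated: attrition and the sampling design of any real cohort, the
joint distribution of covariates (they are independent multinomials used
as adjustment noise), reverse causation from disease to lifestyle,
marker-specific measurement error structure, and any real inter-marker
correlation beyond what the shared acceleration induces. Passing
recovery tests on this generator therefore demonstrates estimator
correctness under the stated model, not robustness to the full
messiness of real cohort data.

Two derived configurations fix their own conditions:

* `cohort_demo_config()` (n = 2000): uniformly negative effects of
  0.7–1.2 years and quarter-scale assay noise, so the all-negative sign
  pattern of the joint fixed-effects fit is recoverable end-to-end at
  moderate sample size. The literature-scale default effects (0.01–0.6
  years) are deliberately *not* used for sign checks at n = 2000: with
  anchored, attenuated outcomes their signs are not identifiable at that
  size, and pretending otherwise would test luck, not code.
* `cohort_recovery_config()` (n = 8000): one shared effect vector across
  all organ systems, quarter-scale noise, scored without the CA anchor.
  Used to verify that recovered mixture shares match the configured
  shares (e.g. diet at 24% of the comprehensive negative mixture,
  smoking at 55% of the metabolic mixture). Magnitudes are scaled
  (×8 / ×10) purely for identifiability; shares are invariant to the
  scaling.

# Numerical choices and degenerate inputs

* Marker residual SDs are floored at $10^{-8}$ and $\hat s_{BA}^2$ at
  $10^{-2}$, so noise-free inputs remain well-defined; a zero-noise,
  zero-effect cohort scores BA = CA to $10^{-8}$ years end-to-end.
* Quintile scoring uses mid-rank positions $(\#\{<x\} + (t+1)/2)/(n+1)$
  with right-closed bins; ties are averaged, and constant components
  score 3.
* Quantile bins in `quantize()` use type-7 empirical quantiles with
  right-closed breaks; duplicate breaks are collapsed.
* Confidence intervals are Wald ($\pm 1.96\,se$) throughout, matching
  the symmetric-CI convention of the analyses reproduced; the QGC
  bootstrap is percentile-based.
* Bit-level reproducibility: one seed drives each generator run, the
  pipeline manifest records MD5 checksums of every artifact, and
  identical configuration plus seed reproduces identical bytes.

# Problem sizes used by the shipped checks

The test suite runs recovery at the scales it states: n = 10,000 records
for biomarker-parameter recovery, n = 8,000 persons across 20 seeds for
the fixed-effects diet-effect and mixture-share recoveries, 100
simulations at n = 2,000 for interval coverage, and an end-to-end
pipeline run at n = 2,000. These sizes give Monte-Carlo error comfortably
inside the asserted bands while keeping a full check run in the
low minutes on one core.

# Known limitations

* Two waves only; no random-effects or hybrid panel models.
* The acceleration outcome is treated as linear in exposures over a
  short interval; no dose-response or nonlinear mixture terms.
* The immune and renal panels are thin (two markers each), so their
  accelerations are noisy and, for renal, unvalidatable by construction
  of the disease map.
* The validation pass rule (any mapped disease with OR > 1 and CI
  excluding 1) is an operationalization of a qualitative published
  conclusion; alternative rules (all diseases, effect-size thresholds)
  are easy to express on the returned report.
* Menopausal status uses a "not applicable" level for men; pooled models
  treat it as an ordinary category.
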