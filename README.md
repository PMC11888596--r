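# orgaging

Multi-organ biological aging and healthy-lifestyle change analysis for
two-wave cohort studies.

## What this package is for

Biological age (BA) estimates, in years, how old a person's physiology
is; it can differ from chronological age (CA), and different organ
systems can age at different rates within one person. `orgaging` is an
analysis toolkit for epidemiologists asking whether *changes* in
lifestyle between two survey waves are associated with changes in
biological aging, overall and per organ system, and which lifestyle
factor contributes most. It provides:

* **Klemera–Doubal biological ages** from 15 routine clinical biomarkers
  — a comprehensive panel plus cardiopulmonary (SBP, PEF), metabolic
  (LDL-CH, HDL-CH, HBA1C, TG, WHR), liver (AST, GGT, ALP, ALB), renal
  (Cr, urea) and immune (PLT, MCV) panels — fit sex-stratified, with the
  uncorrected estimator
  `BA_E = Σ_j (x_j − q_j) k_j / s_j² / Σ_j (k_j/s_j)²`
  and the CA-anchored estimator that adds `CA/s_BA²` to the numerator
  and `1/s_BA²` to the denominator. BA acceleration is `BA − CA`.
* **A five-factor Healthy Lifestyle Index** (smoking, alcohol, diet,
  exercise, sleep; HLI 0–5, healthy = 4–5), with diet scored by a
  modified alternate Mediterranean diet score (7 components, quintile
  scored 1–5, range 7–35), and three-level between-wave change
  categorization per factor.
* **Disease-based validation** of each BA by logistic regression of
  organ-mapped diseases on the standardized acceleration (per-SD odds
  ratios with Wald CIs, ±1 categorization).
* **Two-wave fixed-effects (first-difference) models** of acceleration
  change on lifestyle change with HC1 robust errors, subgroup analyses
  with Cochran's Q heterogeneity tests (α = 0.1), and sensitivity
  variants (standard FEM, BMI adjustment, alternative health
  definitions).
* **Quantile G-computation** on the same differenced design: the mixture
  effect ψ = Σ coefficients, and per-factor relative contributions
  normalized within sign groups (protective weights are the headline).
* **A seeded synthetic two-wave cohort generator** with stored ground
  truth (latent organ accelerations, true effect sizes, implied mixture
  weights), so every estimator has a parameter-recovery test with no
  external data.

The methods vignette (`vignettes/multiorgan-aging.Rmd`) documents the
models, defaults, numerical choices and limitations in detail.

## Worked example

```r
library(orgaging)

cohort <- generate_cohort(cohort_demo_config(n = 2000, seed = 1))
hli    <- classify_lifestyle(cohort$data)
scored <- score_panels(cohort$data)
print(scored$params$comprehensive)
#> Klemera-Doubal parameters for 15 markers
#>   female: n = 1245, r_char = 0.810, s_BA = 2.28 years
#>   male: n = 755, r_char = 0.769, s_BA = 2.11 years

report <- validate_panels(cohort$data, scored$ba, hli)
select_validated_panels(report)$validated
#> [1] "comprehensive"   "cardiopulmonary" "metabolic"       "liver"

fem <- fit_fem(cohort$data, scored$ba, hli,
               fem_spec(panel = "comprehensive", exposure = "factors"))
fem[, c("term", "estimate", "ci_low", "ci_high")]
#>               term estimate ci_low ci_high
#> 1  healthy_smoking   -0.858 -1.222  -0.494
#> 2  healthy_alcohol   -0.547 -0.874  -0.220
#> 3     healthy_diet   -0.404 -0.505  -0.303
#> 4 healthy_exercise   -0.431 -0.559  -0.302
#> 5    healthy_sleep   -0.248 -0.357  -0.139

fit_qgc(cohort$data, scored$ba, hli,
        fem_spec(panel = "comprehensive"), bootstrap_reps = 200, seed = 1)
#> Quantile G-computation (comprehensive): psi = -2.488 (95% CI -2.934, -2.054), n = 2000
#>   negative-direction weights:
#>     smoking    0.345
#>     alcohol    0.220
#>     diet       0.163
#>     exercise   0.173
#>     sleep      0.100
```

Reading the output: the demo cohort is generated with every unhealthy
lifestyle state adding 0.7–1.2 years of latent acceleration, so all five
fixed-effects coefficients on the healthy-flag scale come out negative —
becoming healthy on a factor slows biological aging (e.g. −0.86 years of
comprehensive BA acceleration for quitting-to-never-smoker status, 95%
CI −1.22 to −0.49). The immune and renal panels are absent from the
validated set by construction: the generator links no disease to immune
aging and the disease map contains no renal disease. The QGC mixture
effect says a joint one-step healthier shift in all five factors changes
comprehensive BA acceleration by −2.49 years, with smoking carrying 34%
of the protective mixture in this demo configuration.

`run_pipeline(run_config(...), out_dir)` chains
simulate → score → fit → validate → fem → qgc → report, writing each
stage's CSV/JSON artifact plus a manifest with MD5 checksums; the same
configuration and seed reproduce identical bytes. A thin command-line
wrapper lives at `inst/cli/orgaging.R`
(`Rscript inst/cli/orgaging.R run-all --seed 1 --n 2000 --out runs/demo`).

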