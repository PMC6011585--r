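---
title: "Methods: the mortality risk score, vitamin D status, and their joint survival analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the mortality risk score, vitamin D status, and their joint survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the defaults it chose where the design was genuinely open, and what its
tests do and do not establish.

## The two exposures

**Mortality risk score (MS).** Ten whole-blood CpG probes form the
panel (`ms_panel()`). A sample's score is the number of probes with
aberrant methylation, where "aberrant" means the beta value lies in the
first quartile for nine probes and in the fourth quartile for
cg08362785. Scores are categorised low (0–1), moderate (2–5), high
(>5). Three choices here were under-determined and are pinned by tests:

* *Percentile convention.* Quartile cut-offs use linear interpolation
  between order statistics (the "type 7" rule, R's default). No
  convention was stated for the original cuts; type 7 is the most
  widely used and reproducible choice.
* *Boundary inclusivity.* A beta exactly at the cut counts as aberrant:
  "within" a quartile is read as including its boundary. With
  cohort-derived cuts and tie-free data each probe then flags between
  ⌊n/4⌋ and ⌈n/4⌉ samples.
* *Missing betas.* A sample missing any panel beta gets a missing
  score, not an implicit zero — silent zeros would bias scores (and
  hazard ratios for the high-score categories) downward.

Thresholds are cohort-derived by default (`compute_thresholds()`) but
user-suppliable (`supplied_thresholds()`), because the original
discovery-cohort cuts are not public; whether a given application
should recompute or carry cuts forward is a scientific decision left to
the user.

**Vitamin D status.** Serum 25(OH)D in nmol/L, categorised on
half-open intervals [0, 30) deficiency, [30, 50) insufficiency,
[50, ∞) sufficiency. Concentrations are assumed already standardised
(e.g. to LC-MS/MS); assay calibration is out of scope.

## The survival engine

The Cox proportional-hazards model is estimated by maximising the
partial likelihood with Newton–Raphson. Numerical choices:

* Covariates are centred internally before exponentiation (coefficients
  are unchanged; risk-set sums stay well-scaled).
* Ties: Breslow by default — matching the default of the statistical
  software the original analyses were run in — with Efron available via
  `tie_method`. The two agree to < 1e-10 on tie-free data (tested).
* Step-halving whenever a Newton step would decrease the likelihood;
  at most 50 iterations; convergence requires relative log-likelihood
  change < 1e-9 **and** score sup-norm < 1e-8. Non-convergence is an
  error with diagnostics, never a silent result.
* Constant or collinear columns raise a singularity error naming the
  column; they are not silently dropped. An exposure category with zero
  deaths is reported "non-estimable" rather than as a zero hazard
  ratio, because its partial-likelihood maximiser is −∞.
* Covariance is the inverse observed information; intervals are Wald,
  `exp(coef ± 1.96·se)`; p-values two-sided.

The Breslow baseline cumulative hazard increments by d_j / Σ_{risk}
exp(x'β) at each event time. Direct-adjusted survival curves use the
corrected-group-prognosis construction: one model on group dummies plus
adjustment covariates, then for each group the predicted survival
exp(−H₀(t)·exp(lp)) is averaged over *all* subjects with group
membership forced. With no covariates and one group this reduces
exactly to exp(−Breslow cumulative hazard), which is tested. Follow-up
time starts at study entry; left truncation is not modelled.

The engine is validated two ways: against naive loop-based oracles
(explicit partial likelihood maximised by grid/golden-section and BFGS,
hand-expanded baseline and averaging examples) and against
`survival::coxph` on random datasets to < 1e-6 — the established
implementation serves only as a cross-check in the tests, never as the
computational path.

## Model sequence, screening and joint analyses

Three nested covariate sets (`model_covariate_sets()`): model 1 — age,
sex, season of blood draw; model 2 — plus alcohol (g/day), smoking,
BMI class, physical activity, vitamin supplements, fish consumption;
model 3 — plus prevalent CVD/diabetes/cancer, systolic blood pressure,
CRP, total cholesterol. The full leukocyte composition (five of the six
Houseman-style proportions; granulocytes dropped because the parts sum
to one) is additionally included whenever the MS is in the model. The
mutual model contains both exposures with the model-3 set.

Alcohol enters Cox models as continuous g/day but appears in
descriptive tables as the sex-specific categories (abstainer; low:
women 0–<20, men 0–<40 g/day; intermediate: 20–<40 / 40–<60; high:
≥40 / ≥60) — each context follows its own published convention.

Joint and stratified models adjust only for covariates passing a
bivariable screen against either exposure (chi-square for categorical,
Kruskal–Wallis for continuous; keep when p < 0.2 strictly), plus a
selected leukocyte subset (CD4+ T, CD8+ T, B cells, granulocytes). All
fits are complete-case per model, with analysed n and dropped counts
recorded on every table; no imputation is attempted. A Cochran-Q
(inverse-variance Wald) heterogeneity contrast across strata is
provided as a clearly labelled addition beyond the original analyses.

Categorical reference levels: female, never smoker, under/normal BMI,
medium-or-high activity, "no" for yes/no items, spring, sufficiency,
low MS. Season uses three dummies against spring; the original coding
was not stated.

## Dose-response splines

`rcs_basis()` implements the restricted cubic spline with k knots →
one linear plus k−2 nonlinear columns, each nonlinear column

    [(x−t_j)₊³ − (x−t_{k−1})₊³ (t_k−t_j)/(t_k−t_{k−1})
      + (x−t_k)₊³ (t_{k−1}−t_j)/(t_k−t_{k−1})] / (t_k−t_1)²,

zero below the first knot and linear beyond the last. Knots: 30/50/70
nmol/L for 25(OH)D; the 25th/50th/75th score percentiles (ties merged;
an error if fewer than three survive) for the MS, which is treated as
numeric for spline purposes. The curve is the contrast
basis(x)·β − basis(ref)·β with a delta-method pointwise CI, so the CI
has exactly zero width at the reference. The published figures do not
state their reference values; the defaults are 50 nmol/L (the
sufficiency boundary) and the median score, both configurable.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces, under a single seed, the *marginal*
statistical structure of the emulated 1467-participant cohort of
50–75-year-olds:

* **25(OH)D**: lognormal(μ = 3.83, σ = 0.41) plus a 6 nmol/L
  summer-peaking cosine over blood-draw month, clamped positive —
  giving ≈16/42/43% deficiency/insufficiency/sufficiency and mean
  ≈50 nmol/L. Seasonality is only implied by the original adjustment
  for season; the sinusoid is this package's parametrisation.
* **Panel betas**: a shared standard-normal latent "risk" per subject
  with pairwise correlation 0.33, probe-specific noise, mapped through
  per-probe Beta quantile transforms (Beta(12,4) for the nine
  hypomethylation-aberrant probes, Beta(4,9) for cg08362785), oriented
  so that all aberration flags are positively associated. The
  correlation was calibrated once so the scored levels land near the
  published 41/46/13% low/moderate/high split; the true inter-probe
  correlations and marginals were never published, so these are
  stipulated, not estimated.
* **Survival**: Weibull baseline (shape 1.4, scale 65 years) scaled by
  exp(linear predictor) built from the subject's true vitamin D
  category, true MS level (scored from the generated betas), and any
  configured covariate effects; default true log hazard ratios are the
  published adjusted estimates (1.46, 1.99; 1.87, 3.42). Uniform
  accrual over 0.7 years and administrative censoring at 15.5 years
  yield ≈25% deaths and median follow-up ≈15 years. The Weibull was
  chosen for closed-form inverse sampling; the original baseline is
  unknown. The shape 1.4 encodes the increasing hazard expected in an
  ageing cohort. An `ms_effect_form = "ordinal"` option makes the true
  MS effect log-linear per point, for dose-response calibration tests.
* **Covariates** are drawn independently at the published marginal
  frequencies; leukocyte proportions come from a Dirichlet centred on
  adult whole-blood means (concentration 120). Missingness is injected
  completely at random at the published per-covariate rates (the
  original mechanism was not described).

What it deliberately does **not** emulate: covariate–exposure
correlations (e.g. the real sex and smoking gradients across vitamin D
categories), cause-specific deaths, assay error, recruitment
clustering, or any exposure–covariate confounding. Consequently,
passing recovery tests shows the estimators are correct under
proportional hazards with MCAR missingness — not that the package
would be robust to confounding structures the generator never
produces. Covariate screening on default synthetic cohorts keeps few
candidates, unlike in the real data, precisely because the generator's
covariates are null.

## Problem sizes and calibration checks

The test-suite simulation scales were chosen to keep the Monte-Carlo
error of each check well below its tolerance: single-covariate
recovery at n = 20 000 (tolerance ±0.05 on a log hazard ratio,
asymptotic SE ≈ 0.07/√(events/374)); recovery of the four published
hazard ratios over 50 replicates at n = 5000 (mean within 10%, pooled
CI coverage within [88%, 99%]); null calibration of log-rank and
screening p-values over 500 replicates at n = 400 — large enough that
the chi-square approximation of the log-rank statistic is itself
accurate, so the Kolmogorov–Smirnov check at the 0.01 level measures
the implementation rather than small-sample anticonservatism; spline
honesty under log-linear truth over 10–12 replicates at n = 1200
(nonlinear |z| < 4).

## Known limitations

* No frailty, time-varying effects, competing risks, cause-specific
  endpoints, or left truncation.
* The published headline hazard ratios came from a non-public cohort;
  this package reproduces them only in the sense of parameter recovery
  from synthetic cohorts generated at those truths, plus exact
  reproduction of the fully printed baseline contingency-table
  statistics (`baseline_crosstabs()`).
* Wald intervals can be poor in strata with very few deaths; such
  categories are flagged non-estimable when degenerate, but
  small-count intervals remain wide and approximate.
* The quartile-aberration rule makes scores depend on the cohort used
  for thresholds; supplying external cuts changes the score of any
  given sample.
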