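# epimort

Joint survival analysis of vitamin D status and a blood DNA-methylation
mortality risk score.

## The problem

In older adults, low serum 25-hydroxyvitamin D [25(OH)D] and an
epigenetic "mortality risk score" (MS) — the number of 10 specific
blood CpG sites showing aberrant methylation — are each strong
predictors of all-cause mortality. This package implements the full
analysis pipeline for studying their individual and **joint**
prognostic value in a prospective cohort, for epidemiologists and
biostatisticians who want a tested, reproducible, self-contained
implementation (plus a synthetic cohort generator, since the original
individual-level data are not public).

## What it computes

**Mortality risk score.** For the 10-probe panel (cg01612140,
cg05575921, cg06126421, cg08362785, cg10321156, cg14975410, cg19572487,
cg23665802, cg24704287, cg25983901), aberrant methylation is a beta
value in the first quartile for nine probes and in the fourth quartile
for cg08362785. The MS is the count of aberrant probes (0–10),
categorised low (0–1), moderate (2–5), high (>5). Vitamin D status is
deficiency (<30 nmol/L), insufficiency (30–<50), sufficiency (≥50).

**Survival engine.** A self-contained proportional-hazards
implementation: the Cox partial likelihood

  L(β) = ∏_i [ exp(x_i'β) / Σ_{j ∈ R(t_i)} exp(x_j'β) ]

is maximised by Newton–Raphson with step-halving (Breslow or Efron tie
handling), with the observed-information covariance, the Breslow
baseline cumulative hazard, Kaplan–Meier curves, the log-rank test, and
direct-adjusted ("corrected group prognosis") survival curves
S_g(t) = mean_i exp(−H₀(t)·exp(lp_i(g))).

**Cohort analyses.** Baseline descriptive tables (Kruskal–Wallis /
chi-square), three sequentially adjusted Cox models plus a mutually
adjusted model for both exposures, bivariable covariate screening at
p < 0.2, a joint 3×3 cross-classification model, stratified analyses,
and restricted-cubic-spline dose-response curves (knots 30/50/70 nmol/L
for 25(OH)D; score quartiles for the MS).

**Synthetic cohorts.** `generate_cohort()` draws seeded cohorts with
the statistical structure the analyses assume: seasonal lognormal
25(OH)D (~15/43/41% deficiency/insufficiency/sufficiency), correlated
CpG beta values giving ~41/46/13% low/moderate/high MS, the standard
baseline covariates with leukocyte proportions, and Weibull
proportional-hazards event times with administrative censoring (~25%
deaths, median follow-up ~15 years).

## Worked example

```r
library(epimort)

g  <- generate_cohort(generator_config(seed = 2026))
co <- attach_exposures(g$cohort, g$betas)   # adds vitd_cat, ms_score, ms_level

tab <- fit_hr_table(co, "vitd", model_covariate_sets()$model3)
writeLines(format_hr_table(tab))
```

```
sufficiency                      101/  495  Reference
insufficiency                    132/  508  1.34 (1.03-1.74), p=0.03
deficiency                        64/  190  1.8 (1.3-2.49), p=0.00041
```

Each row is deaths/total and the fully adjusted hazard ratio vs the
sufficiency reference: here insufficient vitamin D carries ~1.3-fold
and deficiency ~1.8-fold mortality. The same call with `"ms"` (and
`leukocyte = "full"`) gives the score's gradient:

```
low                               70/  491  Reference
moderate                         152/  557  2.12 (1.59-2.81), p=2.6e-07
high                              75/  145  5.11 (3.66-7.13), p=8.4e-22
```

A spline dose-response against 25(OH)D, referenced at 50 nmol/L:

```r
dr <- fit_dose_response(co, "vitd", covariates = model_covariate_sets()$model3,
                        grid = c(20, 30, 40, 50, 70, 90))
```

```
  exposure log_hr ci_low ci_high    hr
1       20  0.442  0.083   0.801 1.556
2       30  0.280  0.061   0.499 1.323
3       40  0.124  0.036   0.212 1.132
4       50  0.000  0.000   0.000 1.000
5       70 -0.106 -0.264   0.053 0.900
6       90 -0.168 -0.537   0.201 0.846
```

showing mortality rising steeply below ~40 nmol/L and flat above the
sufficiency threshold. `run_pipeline(pipeline_config(...))` executes
every stage (descriptives → models → joint → stratified →
dose-response → adjusted curves) and writes CSV tables, a log and a
checksummed manifest; `inst/cli/epimort` wraps the same functions as
shell subcommands.

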