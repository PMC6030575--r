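# dailyphq

Psychometric evaluation of **brief daily mood ratings** against a
**periodic multi-item depression questionnaire** in intensive longitudinal
(ecological momentary assessment) designs — the setting of mobile
measurement-based depression care, where a 2-item "how was yesterday"
rating (1–5 scale) is collected daily while the 9-item questionnaire
(PHQ-9, items 0–3) and a 3-item disability scale arrive only every few
weeks.

The package is aimed at biostatisticians and psychometricians working with
this kind of design. It implements, as a tested reusable pipeline:

* **A joint two-level confirmatory factor model**, estimated by
  full-information maximum likelihood. Daily item pairs
  `y_ji = ν + λ_b η_bj + ε_bj + λ_w η_wij + ε_wij` decompose into a stable
  between-person factor and a day-to-day within-person factor; the
  questionnaire follows a single-level factor model
  `z_j = τ + Λ ξ_j + δ_j`; and the validity parameter is the latent
  correlation `r = Cor(η_b, ξ)`. Latent means are fixed at 0 and variances
  at 1; the two daily items share one loading per level. Unbalanced
  clusters (1–14 ratings per person) are handled exactly by the
  person-marginal Gaussian likelihood; chi-square, CFI, TLI and RMSEA come
  from companion saturated (80-parameter) and independence (24-parameter)
  fits.
* **Level-specific reliabilities**: composite omega
  `(Σλ)²ψ / [(Σλ)²ψ + Σθ]` for the questionnaire and for the within-person
  (day-to-day) daily composite, and the person-mean reliability of the
  daily composite over `n̄` days,
  `(Σλ_b)²ψ_b / [(Σλ_b)²ψ_b + ΣΘ_b + ((Σλ_w)²ψ_w + ΣΘ_w)/n̄]`, with
  delta-method 95% CIs.
* **Measurement-invariance tests** across binary demographic splits:
  likelihood-ratio comparison of unconstrained vs constrained (equal
  loadings/intercepts/residuals, second-group latent variances re-freed)
  multiple-group fits, with degrees of freedom counted symbolically from
  the parameterization (32 at the 9-item roster).
* **Outcome prediction by seemingly unrelated regression**: per-person
  summaries of the daily composite (mean, SD, min, max, linear slope over
  calendar days) feed four predictor rosters for the two week-8 outcomes,
  fitted jointly by two-step (optionally iterated) feasible GLS.
* **A synthetic-cohort generator** reproducing the reference study
  conditions — 545 persons, the empirical 1–14 ratings-per-person
  distribution (2992 ratings, mean 5.5), reference measurement parameters
  with latent correlation 0.80, baseline eligibility truncation
  (sum ≥ 5, post-truncation mean 13.9, SD 5.0), calibrated week-8 outcome
  R² (0.49 / 0.37) and 35% MCAR week-8 missingness — so every stage is
  testable without restricted trial data.

See `vignettes/daily-questionnaire-reliability.Rmd` for the model,
assumptions, numerical choices and limitations.

## Worked example

```r
library(dailyphq)

cohort <- generate_cohort(generator_config(), seed = 11)
flt <- apply_sample_filters(cohort$daily, cohort$panel)

fit <- fit_mlcfa(flt$daily, flt$panel)
print(fit)
#> Joint two-level factor model fit (FIML)
#>   persons: 545, free parameters: 36
#>   log-likelihood: -11926.088 (converged: TRUE)
#>   latent correlation r = 0.818

reliability_report(fit, n_bar = "auto")
#>              quantity estimate      se lower upper n_bar
#> 1 omega_questionnaire    0.888 0.00720 0.874 0.902  5.49
#> 2        omega_within    0.813 0.00755 0.798 0.827  5.49
#> 3         rho_between    0.868 0.00920 0.849 0.886  5.49

summ <- summarize_daily(flt$daily)
mm <- build_model_matrices(flt$panel, summ, model_id = 1)
fit_sur(mm$X, mm$Y)
#> Seemingly unrelated regression (FGLS), n = 341
#>   phq9_wk8: R2 = 0.552
#>             estimate     se      p
#> (Intercept)   0.8071 0.3704 0.0293
#> phq9_week4    0.7606 0.0371 0.0000
#>   sds_wk8: R2 = 0.347
#>             estimate     se      p
#> (Intercept)   2.5771 2.0361 0.2056
#> phq9_week4    2.7479 0.2041 0.0000
```

Reading the output: the latent correlation 0.82 (generated at 0.80) says
the stable trait behind the daily ratings is nearly the questionnaire's
trait; the three reliabilities say a person's two-week daily average
(0.87) is about as reliable as the questionnaire itself (0.89), while a
single day's deviation is somewhat noisier (0.81); and the week-4
questionnaire sum alone explains 55% / 35% of week-8 depression /
disability variance in this simulated cohort of 341 complete cases.

## The analysis workflow

`analysis/` holds the pipeline as numbered stage drivers, each a thin
script over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 11   # cohort tables + provenance
Rscript analysis/02_fit_mlcfa.R            # joint fit + fit indices
Rscript analysis/03_reliability.R          # omegas + person-mean reliability
Rscript analysis/04_invariance.R           # 3 LRTs + per-group tables
Rscript analysis/05_predict.R              # 4 SUR models
Rscript analysis/06_report.R --seed 11     # one-command consolidated report
```

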