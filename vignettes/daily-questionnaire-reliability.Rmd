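---
title: "Joint two-level factor analysis of daily mood ratings and a periodic depression questionnaire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint two-level factor analysis of daily mood ratings and a periodic depression questionnaire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Mobile mental-health studies increasingly collect a very short depressed-mood
measure every day — here, the first two items of the 9-item depression
questionnaire (PHQ-9), recast to ask about "yesterday" on a 1–5 scale —
alongside the full questionnaire every few weeks. Before daily ratings can
drive measurement-based care, two psychometric questions must be answered:

1. **Reliability.** How reliable is a single day's rating, and how reliable
   is a person's *average* over a couple of weeks of (irregularly completed)
   ratings?
2. **Validity and utility.** How strongly does the latent trait behind the
   daily ratings correlate with the questionnaire's latent trait, and do
   daily-rating summaries predict later outcomes as well as the
   questionnaire does?

`dailyphq` implements the full analysis pipeline for this design, plus a
synthetic-cohort generator so that every stage can be exercised and tested
at desk scale — the motivating trial's raw data are not publicly deposited.

## The joint model

Let person $j$ contribute $n_j \in \{1,\dots,14\}$ daily item pairs
$y_{ji} \in \mathbb{R}^2$ inside the 14-day window preceding the anchor
questionnaire, and one questionnaire item vector $z_j \in \mathbb{R}^9$ at
the anchor week. The model couples

* a **two-level factor model** for the daily items: at the between-person
  level a stable factor $\eta_{bj}$ with loading $\lambda_b$ (shared by
  both items), intercepts $\nu$, and residuals
  $\varepsilon_{bj} \sim N(0,\Theta_b)$ shared across a person's days;
  at the within-person level a day factor $\eta_{wij}$ with shared loading
  $\lambda_w$ and day residuals $\varepsilon_{wij} \sim N(0,\Theta_w)$:
  $$y_{ji} = \nu + \lambda_b \eta_{bj} + \varepsilon_{bj}
            + \lambda_w \eta_{wij} + \varepsilon_{wij};$$
* a **single-level factor model** for the questionnaire:
  $z_j = \tau + \Lambda\, \xi_j + \delta_j$,
  $\delta_j \sim N(0,\Theta)$;
* a **latent correlation** $r = \mathrm{Cor}(\eta_b, \xi)$, the key
  validity parameter.

Identification follows the convention of fixing all latent means to 0 and
latent variances to 1, and equating the two daily items' loadings within
each level (with only two indicators per level the loadings are not
separately identified). The two daily items' intercepts and residual
variances are free by default; `model_spec(equal_daily_items = TRUE)`
equates them as well.

### Estimation: full-information ML on the person-marginal likelihood

Integrating the latents analytically, each person's observed vector is
multivariate normal with

$$\mathrm{Cov}(y_{ji}, y_{ji'}) = \Sigma_b = \lambda_b\lambda_b^\top + \Theta_b
  \;(i \ne i'), \qquad
  \mathrm{Cov}(y_{ji}, y_{ji}) = \Sigma_b + \Sigma_w, \qquad
  \mathrm{Cov}(z_j, y_{ji}) = \Lambda\, r\, \lambda_b^\top,$$

and the likelihood is the product of these person-marginal densities —
exact full-information ML, which handles the heavily unbalanced cluster
sizes (1–14 ratings per person) without the balanced-data approximations of
classical two-matrix multilevel SEM estimators. Persons missing one block
(no questionnaire, or no daily rows) contribute the marginal density of
their observed block.

Because days are exchangeable under this covariance structure, the package
evaluates the likelihood through an exact orthogonal reduction: each
person's days split into $n_j - 1$ iid $N(0, \Sigma_w)$ within-contrasts
(entering only through a pooled within-person scatter matrix) and the
11-dimensional vector $(z_j, \bar y_j)$ with
$\mathrm{Cov}(\bar y_j) = \Sigma_b + \Sigma_w / n_j$. Grouping persons by
(questionnaire present, $n_j$) and caching each group's mean and scatter
makes one likelihood evaluation independent of the number of persons. The
reduction is validated in the test suite against a naive dense-covariance
evaluator (`dense_loglik()`) to $10^{-8}$ on small unbalanced instances
with missing blocks.

### Fit indices

`fit_saturated()` maximizes the same marginal likelihood under an
unrestricted structure — an arbitrary positive-definite 11×11 between-level
covariance (Cholesky-parameterized), an arbitrary 2×2 within-level
covariance, and 11 free means, 80 parameters in all — and
`fit_baseline()` fits the diagonal independence model (24 parameters).
CFI, TLI and RMSEA then follow their standard definitions from the two
chi-squares; the RMSEA sample size is the number of *persons*, the
independent units. With only 36 free parameters in the structured model the
model-vs-saturated test has 44 degrees of freedom.

## Reliability

Three quantities summarize measurement precision, all derived from the
fitted (or any supplied) parameter set:

* **Questionnaire omega** — the composite reliability
  $(\sum\lambda)^2\psi / [(\sum\lambda)^2\psi + \sum\theta]$ over the nine
  items.
* **Within-person daily omega** — the same formula applied to the
  within-level daily parameters: the reliability of a single day's
  deviation from the person's own average.
* **Person-mean reliability** — the reliability of a person's average
  daily composite over $\bar n$ days,
  $$\rho(\bar n) = \frac{(\sum\lambda_b)^2\psi_b}
    {(\sum\lambda_b)^2\psi_b + \sum\Theta_b +
     [(\sum\lambda_w)^2\psi_w + \sum\Theta_w]/\bar n},$$
  which is increasing in $\bar n$ and bounded by the level-specific
  between omega. With the bundled reference parameters and the reference
  cohort's $\bar n = 2992/545 = 5.49$ this evaluates to 0.855; the
  *arithmetic* mean cluster size is the default because it is the unique
  choice that reproduces the published value from the published parameter
  table (the harmonic mean, available via `n_bar_type = "harmonic"`, gives
  a smaller, more conservative value). Evaluating the within-level omega
  on two-decimal-rounded published parameters gives 0.813 where the
  unrounded fit printed 0.82 — a reminder that arithmetic on rounded
  tables carries roughly ±0.01 of slack.

95% CIs are delta-method intervals: the gradient of each reliability with
respect to the transformed free parameters is numerically differentiated
and propagated through the inverse-Hessian covariance of the fit.

## Measurement invariance

For a binary demographic split, the **unconstrained** model estimates every
measurement parameter and the latent correlation separately per group
(equivalently two independent fits); the **constrained** model equates all
loadings, intercepts and residual variances across groups. Once loadings
are equated, fixing both groups' latent variances to 1 would conflate
variance differences with loading differences, so the second group's three
latent variances are re-freed (standard invariance practice); the latent
correlation stays group-specific in both models. The likelihood-ratio
degrees of freedom are counted from the parameter packings themselves,
never hard-coded; at the 9-item roster the comparison has
$2 \times 36 - 40 = 32$ degrees of freedom. This is the unique convention
consistent with all published tests of this design that we are aware of;
the naive "constrain everything, keep variances fixed at 1" count would
give 35. The test suite calibrates the procedure under the null: at a
reduced roster (2 questionnaire items, 60 persons/group, clusters of 1–4
days) the LRT statistic over 200 seeded replicates is consistent with its
reference chi-square distribution (Kolmogorov–Smirnov, $\alpha = 0.01$).

One consequence of re-freeing the second group's latent variances is worth
knowing: a *uniform* scaling of one group's loadings is nearly equivalent
to a latent-variance change and is therefore largely absorbed by the
constrained model — the test is sensitive to intercept shifts and
non-proportional loading differences, not to a proportional rescaling of a
whole block. This mirrors the usual indeterminacy between loading scale
and factor variance.

## Predicting later outcomes

Each person's in-window daily composites (the mean of the two items) are
summarized by mean, SD, minimum, maximum and least-squares slope; the
slope regresses on the calendar day offset, so gaps between ratings
matter, and SD/slope are undefined below two rating days. Four predictor
rosters — anchor questionnaire sum only; daily mean only; both; all five
daily summaries — are fitted for the two week-8 outcomes (questionnaire
sum and disability sum) jointly by **seemingly unrelated regression**:
per-equation OLS, ML residual covariance, then joint feasible GLS
(optionally iterated). Because all four models use identical
regressors in both equations, the SUR point estimates coincide with OLS
(Kruskal's theorem) — asserted in the tests to $10^{-10}$ — while the
cross-equation residual covariance is still estimated and reported.
Listwise deletion of persons missing any required predictor or either
outcome, with SD/slope availability binding only in the five-summary
model, makes the analysis N differ across models, as in the motivating
design.

The daily composite is the *mean* of the two items rather than their sum,
so slopes and SDs stay on the 1–5 item scale; this is a scale convention
only and does not affect R².

## The synthetic-cohort generator

`generator_config()` defaults encode the reference study conditions:

| quantity | default | note |
|---|---|---|
| persons | 545 | reference cohort size |
| ratings/person | exact empirical multiset, mean 5.49 | `"fixture"` mode; a probability table is also accepted |
| day placement | uniform without replacement in the 14-day window | placement is not reported for the reference cohort; an assumption |
| measurement parameters | bundled reference estimates | loadings/intercepts/residuals for 9 + 2 items |
| latent correlation | 0.80 | reference value |
| baseline sum | post-truncation mean 13.9, SD 5.0, floor 5 | truncated-normal, pre-truncation mean calibrated by root-finding |
| group labels | Bernoulli: 78.3% women, 38.1% minority, 6.1% aged 55+ | independent draws; invariance holds unless offsets are configured |
| week-8 outcomes | linear in the anchor-week sum, residual variances calibrated to population R² 0.49 / 0.37 | cross-equation residual correlation 0.3 |
| week-8 missingness | 35% MCAR | produces analysis Ns near 65% of the cohort |

Indicators are *continuous* (normal-theory) by default so that sample
moments converge to model-implied moments; `discretize = TRUE`
rounds-and-clips to the ordinal scales (1–5 daily, 0–3 questionnaire),
which attenuates covariances — the tests assert the attenuation but all
calibration claims are made in continuous mode. Baseline scores are
generated independently of the week-4 latent structure (the reference
study reports baseline only descriptively). A per-person truth table
(latent scores, cluster sizes) is retained for recovery tests.

What the generator does **not** emulate: ordinal response styles and
floor/ceiling effects, time-of-day or day-of-week response patterns,
informative (non-MCAR) missingness, autocorrelated day factors, and any
association between baseline severity and later latents. Passing tests
therefore demonstrate correctness of the estimators under the stated
generating model, not robustness to those real-data features.

## Numerical choices

* **Transforms.** Variances are optimized on the log scale, correlations
  via $\tanh^{-1}$; the saturated covariances via Cholesky factors with
  log diagonals. All reported estimates and SEs are mapped back by the
  delta method.
* **Starting values.** Intercepts start at item means, residual variances
  at half (questionnaire) or a quarter (each daily level) of the item
  variances, $r$ at 0, and loadings at *half an item SD*. Scale-free
  constant starts (e.g. 0.5) proved fragile: after rescaling the daily
  items they can send the quasi-Newton search to a boundary local optimum
  with $|r| \to 1$; SD-proportional starts make the whole fit equivariant
  under item rescaling, which the test suite asserts (loadings and
  residual SDs scale by $c$; $r$ and chi-square are unchanged).
* **Convergence.** BFGS (finite-difference gradients) with relative
  tolerance $10^{-12}$, up to 500 iterations, restarted from its own
  optimum until the objective stops improving; a fit is flagged converged
  when the final numeric gradient max-norm is below
  $10^{-4}(1 + |\ell|)$ — an absolute $10^{-6}$ criterion is not
  attainable with finite-difference noise on log-likelihoods of magnitude
  $10^4$. Estimates of $|r| > 0.999$ are flagged as boundary solutions.
* **Degenerate inputs.** Non-positive-definite proposals during
  optimization are rejected by the line search (objective $+\infty$);
  user-facing evaluators raise an error naming the offending block.
  Duplicate person-day rows are integrity errors, not averaged. A rating
  on the anchor day itself is outside the window $[a-14, a)$, because the
  daily items ask about "yesterday" while the questionnaire covers the
  preceding two weeks; the anchor day is `7 * anchor_week` for every
  person (the generator completes questionnaires on schedule).

## Problem sizes used by the test suite

Module tests run on cohorts of 5–800 persons with clusters of 1–5 days;
the calibration checks use 20 000 persons for moment-level claims
(R², truncated-baseline mean, generator moments), 20 seeded cohorts of
545 persons for latent-correlation recovery, 20 cohorts of 2000 persons
for SE-coverage, and 200 replicates of a reduced two-item roster for the
null LRT calibration. These sizes were chosen so each claim's Monte-Carlo
error is well inside the asserted tolerance.

## Known limitations

* Normal-theory ML treats 1–5 and 0–3 ordinal responses as continuous;
  categorical/threshold estimation is out of scope, so fitted loadings on
  real ordinal data would be mildly attenuated relative to a threshold
  model.
* Robust (sandwich) and scaled test statistics are not implemented; the
  chi-square and its indices are plain ML quantities.
* Exactly two groups per invariance comparison; no partial-invariance
  search.
* The person-mean reliability uses a single cohort-level $\bar n$; a
  per-person version would require reporting a distribution rather than a
  scalar.
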