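---
title: "Measuring faking ability: models, scoring and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring faking ability: models, scoring and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Applicants routinely distort self-report personality questionnaires toward
what they believe a job demands. Most research quantifies how *much*
responses shift (faking extent); this package implements the complementary
view of faking as an *ability*: a skill scored against a veridical target.
The veridical target for a job is its **optimal personality profile** — the
mean of expert ratings per item of a work-style questionnaire, or the
regression projection of those ratings onto a second, linked questionnaire.
A respondent instructed to fake for a given job is then scored by how close
their response vector comes to that profile.

The package covers the whole chain: questionnaire linkage, profile
projection, profile-similarity scoring, latent measurement models of the
two resulting abilities, and structural models that regress them on
cognitive abilities. A synthetic-data generator with known parameters makes
every stage testable end to end, since no respondent-level data of this
kind are publicly deposited.

## Linkage and optimal profiles

The anchor instrument is a 16-item work-style questionnaire rated 1–5; the
target instrument is a large Big-Five item pool. On an honest sample
(default n = 151) each anchor item is correlated with every target item,
and the eight target items with the highest correlation form that work
style's subscale. If fewer than eight items reach a moderate correlation
(r = 0.3), no subscale is created. Two open choices are resolved as
follows and are switchable:

* **Ranking statistic.** Ranking and thresholding use |r| by default
  (`statistic = "abs"`), because reversed indicators are substantively
  valid markers of a work style; signed ranking is available.
* **Ties** at the k-th rank break by target-item column order, making
  selection deterministic and order-invariant up to that documented rule.

Per selected pair, ordinary least squares gives target = a + b·anchor; the
item-level optimal value for a job is a + b·(mean expert rating), clipped
to the response scale if the projection leaves it (values outside the
bounds are possible because the line is unconstrained; clipping to the
scale bound is the recommended adjustment and is what `project_optimal_profile`
does, retaining the raw value alongside).

## Profile-similarity scoring

Faked responses are collected on a 50-point slider so they can be compared
against fractional optimal values, then divided by 10 onto the anchor
scale. Two metrics are computed per task:

* **Elevation**: |mean(response) − mean(optimal)|, square-root transformed.
  Absolute difference scores are right-skewed by construction; the square
  root improves distributional properties for the latent models. Lower
  values indicate higher ability.
* **Shape**: the Pearson correlation between response and optimal vectors.
  Higher values indicate a better pattern match. A zero-variance response
  vector leaves the correlation undefined and the value is set to missing;
  a zero-variance *optimal* vector is also missing but warned about, since
  it marks a degenerate task rather than a respondent behavior.

Target-instrument tasks consist of four disjoint 8-item subscales. Whether
the original procedure scored such tasks over all 32 items at once or per
subscale is ambiguous; both are implemented (`mode = "pooled"` /
`"subscale"`), and the default scores per subscale and averages the
available subscale values, because the measurement models use one
indicator per task and disjoint subscales are the least-assumptive bridge
between item- and task-level scores. Task-level shape is missing only when
all four subscale shapes are missing.

Descriptive summaries report mean, SD, min, max, skew and excess kurtosis
without small-sample bias corrections, matching the near-zero reference
values of roughly normal scores.

## The latent-variable engine

No structural-equation package is part of the compute environment, and the
covariance-structure machinery is deliberately a first-class, compact
implementation here. A model is Λ, B, Ψ, Θ in the usual all-latent form,

Σ(θ) = Λ (I − B)⁻¹ Ψ (I − B)⁻ᵀ Λᵀ + Θ,

with free error covariances and factor covariances by name and
orthogonality as the default. Identification uses **effects coding**: each
factor's loadings are constrained to average 1 (the last loading is
determined as n_f − Σ others), leaving the factor variance free — so factor
variances are estimated on the natural metric of their indicators and no
single marker item dominates the scaling. A marker option exists.

Numerical choices:

* **Complete data** minimize F = ln|Σ| + tr(SΣ⁻¹) − ln|S| − p with S the
  divisor-n covariance; **missing data** use casewise (full-information)
  maximum likelihood over missing-pattern groups, with saturated means.
  Both routes report χ² = (n − 1)·F (for FIML, (n − 1)/n · 2(ℓ_sat −
  ℓ_model), with the saturated log-likelihood from an EM algorithm for the
  unstructured multivariate normal). This single convention makes the two
  routes agree exactly on complete data.
* Gradients of both objectives are analytic (∂F/∂Λ = 2EΛC and its
  companions, chained through the effects-coding constraint), which keeps
  quasi-Newton iterations cheap and exact; tests verify them against
  central finite differences.
* Optimization is `nlminb` from up to three deterministic starts
  (moment-based, identity-scaled, perturbed) with an objective tolerance of
  1e-12; a solution also counts as converged when its scaled gradient
  norm is below 1e-4, which absorbs the optimizer's spurious "singular
  convergence" report at flat optima. Non-convergence after all starts is a
  diagnostic error, never silently ignored.
* Inadmissible trial points (non-positive-definite Σ) get a large penalty
  value; **Heywood cases** at the solution (negative variance estimates)
  are reported in the fit object, not clipped.
* CFI uses the independence baseline with free variances (FIML: free means
  and variances, available-case closed form); RMSEA = √(max(χ²−df,0) /
  (df·(n−1))) without small-sample corrections.
* Standard errors come from the inverse numerical Hessian (finite
  differences of the analytic gradient), with delta-method SEs for
  determined loadings. Substantive inference in the pipeline relies on
  likelihood-ratio tests and the bootstrap rather than Wald tests, because
  Wald statistics depend on how the model is identified.

**Reliability** is McDonald's ω = (Σλ)²φ / [(Σλ)²φ + Σθ_ii + 2Σθ_ij] per
factor, with error covariances among the factor's indicators entering the
denominator.

**Boundary-adjusted LRTs.** When a single parameter is tested at the edge
of its admissible space, the null distribution of T = 2Δℓ is the 50:50
mixture of a point mass at zero and χ²(df); the p-value halves. The
notation χ²(0.5) in this literature is ambiguous between that mixture and
a fractional-df χ², and the quoted critical value 3.841 is the plain χ²₁
value — the two adjusted readings would give 2.706 or less. All three are
available: `boundary = FALSE` (plain), `boundary = TRUE` with
`method = "mixture"` (default adjustment) or `method = "fractional"`.

**Bootstrap.** Nonparametric case resampling with percentile intervals
(default 1000 draws), refit from the full-sample solution; non-converged
draws are dropped and counted, with a warning above 20% (an error in
strict mode).

**Model zoo.** `builtin_model_zoo()` ships the final topologies: the
5-indicator elevation model (the anchor-instrument pilot task is excluded,
after its negative loading; the two remaining anchor-instrument tasks share
an error covariance capturing method variance), the 6-indicator shape model
with the same covariance, the correlated two-factor model, the cognitive
bifactor (g on 11 parcels with fluid reasoning as the reference ability —
the fluid parcels load on g only — plus nested orthogonal crystallized and
emotion-perception factors), and the two structural models regressing each
ability on g, gc and ep. Because the bifactor predictors are orthogonal,
the standardized weights are interpretable as correlations and R² = Σγ²
holds exactly in the standardized solution.

## Correlation-difference tests and power

Standardized weights of orthogonal predictors are compared with Fisher
r-to-z difference tests, z = (atanh r₁ − atanh r₂)/√(2/(n−3)), one-tailed
by default. The independent-samples formula with common n is the default
even where the compared weights share a variable: the shape–elevation
factor correlation is small and non-significant, and the published test
statistics are consistent with ignoring the dependence; a
Steiger-adjusted dependent variant is provided (`method = "dependent"`).
Power and sensitivity use the same approximation: power = Φ(atanh(r)·√(n−3)
− z_crit) and its closed-form inverse. At n = 210, α = 0.05 and power
0.80 the minimal detectable correlation is r = 0.19.

## The synthetic-data generator

The generator emulates the study conditions: 299 recruited respondents of
whom 89 fail at least one of three attention checks (leaving 210), panels
of 25 experts per job for three jobs with distinct work-style patterns
(the true anchor profiles embed the published mean expert ratings of the
administered subscales, e.g. pilot self-control 4.7), an honest linkage
sample of 151, and cognitive parcels with a bifactor structure. The
structural truth is γ = (0.218, 0.495, 0.316) of (g, gc, ep) on the shape
ability and zero on elevation.

The response **mechanism** is invented, because the original study
measured rather than simulated faking. Choices:

* A respondent's centred response pattern is a convex blend of the centred
  optimal pattern and a respondent-specific noise pattern; the blend
  weight is a logistic function of the task-specific shape latent
  (`w = plogis(0.1 + 0.9·s)`), giving continuous, monotone control of the
  pattern match with exact limits (weight 1 → shape score 1).
* The response mean overshoots the optimal mean by a scaled negative
  exponential of the elevation latent (`0.5·exp(−0.6·e)`), which is
  positive, monotone and vanishes for perfect fakers.
* Task-specific latents load 0.5 (anchor-instrument tasks) / 0.7
  (target-instrument tasks) on the respective ability, reflecting that the
  longer target-instrument tasks are the stronger indicators.
* Expert rater noise is truncated normal on the 1–5 scale, recentred so
  the panel mean equals the true profile value (plain truncation would
  bias means near the scale bounds); panel means are therefore rational
  numbers, as in occupational-database ratings.
* One master seed fans out into per-stage sub-seeds through a
  deterministic arithmetic hash, so each stage is individually
  reproducible and the whole study is bit-reproducible.

The mechanism constants were fixed once, upfront, so that the generated
scores show the qualitative structure the pipeline assumes — positive
factor loadings, mid-scale shape scores with spread, the γ pattern above,
and a zero-variance shape missingness rate of about 1% — and were not
revisited. The generator does **not** attempt to reproduce the published
per-task score moments, response-style artifacts (acquiescence, central
tendency), task-order effects, or the honest-condition analyses. Passing
tests therefore show that the pipeline recovers known structure from data
of this general shape, not that the mechanism matches human faking
behavior.

## Problem sizes

The test suite and acceptance script choose sizes that balance
Monte-Carlo error against runtime on a single CPU: generator fidelity and
end-to-end recovery use n = 2000 (recovery tolerance ±0.08 on standardized
weights); the acceptance recovery run uses n = 6000; confidence-interval
coverage uses 100 replications at the study's own n = 210; the
likelihood-ratio-test size check uses 1000 replications of n = 500; the
bifactor covariance convergence check uses n = 50000.

## Known limitations

* The engine is deliberately compact: no ordinal/weighted least squares
  estimation, no mean-structure modeling beyond what FIML requires, no
  modification indices (final topologies are shipped instead), and no
  non-recursive structural parts.
* FIML assumes missing-at-random; the zero-variance shape rule is
  plausibly related to low ability, so at high missingness rates this
  assumption would bite. At the ~1% rates generated here its effect is
  negligible.
* Wald-style Hessian intervals are used in simulation-based coverage
  checks for speed; substantive intervals should use the bootstrap.
* The linkage stage selects items by correlation only; it does not
  re-validate subscales with per-subscale factor models against the anchor
  item, which would require the original honest-sample data.
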