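---
title: "Synthetic occupation-based wage estimation: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic occupation-based wage estimation: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthwage)
```

## The problem

Income predicts many health outcomes, so it is an important confounder to
control for in epidemiological models — but it is also among the worst
measured variables in surveys: sensitive, complex to report, often missing
for 10–25% of respondents, and sometimes not asked at all. Occupation, by
contrast, is cheap to collect, rarely missing, and — when coded to a tiered
standard occupational classification (SOC, ISCO, and similar schemes) —
highly discriminating with respect to pay.

`synthwage` turns that observation into an estimator: it fits a model of
wages on a large reference survey where both wages and occupation codes are
observed, and then *transfers* the fitted model into any target survey that
records only age, sex and occupation, assigning each respondent a synthetic
weekly wage. The synthetic wage can stand in for reported income as a
continuous measure of socio-economic position.

## The model

Occupation codes in a tiered classification nest by prefix: 4-digit *unit*
groups (e.g. `1121`) sit inside 3-digit *minor* groups (`112`), which sit
inside sub-major (`11`) and major (`1`) groups. The wage model exploits the
two finest tiers. For individual $i$ in unit group $u$ nested in minor
group $m$:

$$
\log w_{i} \;=\; \beta_0 + \beta_a\,\mathrm{age}_i + \beta_s\,\mathrm{male}_i
\;+\; u_m + a_m\,\mathrm{age}_i \;+\; v_u + b_u\,\mathrm{age}_i
\;+\; \varepsilon_i
$$

with independent Gaussian random effects
$u_m \sim N(0, \tau^2_{m0})$, $a_m \sim N(0, \tau^2_{m1})$,
$v_u \sim N(0, \tau^2_{u0})$, $b_u \sim N(0, \tau^2_{u1})$ and residual
$\varepsilon_i \sim N(0, \sigma^2)$. Four nested configurations are
provided: `M1` (minor intercepts only), `M2` (minor intercepts and age
slopes), `M3` (minor and unit intercepts), and `M4` (all four terms — the
default, and the configuration that wins the internal validation on data
with genuine unit-level structure). Intercepts and slopes at the same tier
are modelled as mutually independent; an intercept–slope covariance adds a
parameter the two-tier structure rarely supports and is deliberately
excluded.

The fixed covariates are restricted to age and sex by design: the whole
point of the method is that the model can be re-applied in any survey, and
age, sex and occupation are close to universally available.

### Estimation

Parameters are estimated by maximum likelihood (REML is available behind
`fit_control(reml = TRUE)` for sensitivity analysis, but ML is the
criterion of record). Observations in different minor groups are
independent, so the marginal likelihood factorises over minor-group blocks;
within a block the covariance is
$\sigma^2 I + Z G Z'$ with at most $2 + 2k$ random-effect columns for $k$
unit groups. All block computations use the Woodbury identity on
pre-computed crossproducts, so one likelihood evaluation costs
$O(q^3)$ per block regardless of the number of observations — a 50,000-row
fit takes a few seconds on one core.

The optimiser works on log standard deviations (guaranteeing positivity),
with the fixed effects profiled out by generalised least squares at every
variance iterate, leaving at most a five-dimensional problem. Two starting
points (a moment-based start and a small-variance start) guard against
local optima and ensure that a richer configuration never scores below a
nested one; a quasi-Newton polish pass tightens the optimum so nesting
holds to $10^{-6}$ on the log-likelihood. Convergence is assessed on the
log-likelihood with default tolerance $10^{-8}$. Variance estimates below
$10^{-10}$ are truncated to exactly 0 and flagged as boundary estimates —
with a generatively-zero component this is the expected, correct outcome,
not a failure.

### Empirical Bayes shrunk residuals

Prediction uses the posterior means (BLUPs) of the group effects, solved
exactly per minor-group block. In the one-level case the familiar form

$$\hat u_m = \frac{n_m \tau^2}{n_m \tau^2 + \sigma^2}\,\bar r_m$$

shows the behaviour that makes the method robust for small occupations:
a group observed many times keeps nearly its raw mean residual, while a
group observed once or twice is pulled towards 0, the prior mean. The
package verifies this closed form exactly, and verifies the general solver
against a joint Henderson mixed-model-equations solve on dense test
problems.

## Preprocessing

`build_master()` applies, in order: complete-case restriction on wage, age,
sex and occupation; the working-age filter (16–65 for men, 16–60 for women,
bounds inclusive — outside these ranges occupation stops being a reliable
guide to earnings); the employment filter (respondents out of work carry no
current occupation code); CPI standardisation of all wages to a reference
year (annual indices, multiplicative rescaling); outlier trimming; and the
log transform. Every stage's drop count is recorded.

Outlier handling is deliberately algorithmic rather than judgemental:
first a quantile trim (defaults 0.1% and 99.9%, inverse-ECDF quantiles so a
small clean sample is never trimmed), then, if the sample skewness of log
wage still exceeds 1.0 in absolute value, iterative removal of the value
farthest from the running median of log wage, capped at 1% additional
removals. All three knobs sit in `trim_policy()`. Two properties are worth
knowing. First, the procedure is deterministic, including its tie-break
(first index wins). Second, trimming the tails of the *pooled* wage
distribution is not neutral with respect to covariates: it preferentially
removes high-earning men and low-earning women, which attenuates the
fitted sex effect by a few thousandths of a log-point in our simulations.
This is a property of any pooled tail trim, and the reason the package's
parameter-recovery tests feed the estimator untrimmed data.

## Prediction and the fallback ladder

`transfer()` assembles each prediction from the fixed part plus the EB
residuals of the record's groups. Occupations never seen in training fall
back tier by tier to the EB prior mean of 0: an unseen unit group keeps its
minor-group terms (`fallback_tier = "minor"`); an unseen minor group uses
the fixed part alone (`"fixed-only"`). This is the natural Empirical Bayes
answer — no data about a group means predicting its prior mean — and it
keeps the transfer total: no record errors out. The same ladder handles
target surveys whose codes are only recorded at minor tier.

The pound-scale prediction is the naive exponential of the log-scale
prediction, i.e. a geometric-mean-consistent estimate, which is the scale
the internal validation's geometric-mean baselines live on. A lognormal
smearing factor $\exp(\hat\sigma^2/2)$ is available (`smearing = TRUE`) for
users who want an arithmetic-mean-consistent wage, but it is off by
default. Predictions are at reference-year prices by construction and are
not re-inflated.

## Internal validation

The training survey is split by year: the reference year is held out, the
model is fitted to the remaining years, and each predictor is scored by the
standard deviation of its pound-scale residuals on the holdout. Two
baselines anchor the comparison: the grand geometric mean wage (one number
for everyone) and per-unit-group geometric means (occupation information
without any model). The report also shows each predictor's percent
reduction of deviation relative to the grand baseline, computed on the
variance scale:

$$\text{reduction} = 100\left(1 - \left(\frac{d}{d_0}\right)^2\right)\%$$

so a predictor that halves the deviation achieves a 75% reduction, not
50%. A root-mean-square option (`method = "rms"`) is provided for users who
want bias to count against a predictor; the default SD is shift-invariant.

On synthetic data with genuine unit-level structure the expected ordering —
grand baseline worst, per-unit geometric means better, the full model best
— is reproduced by the test suite and the acceptance script. Notably the
per-unit geometric mean baseline beats the minor-level-only models `M1` and
`M2`: occupation detail at the unit tier is worth more than age and sex on
top of coarse occupation.

## External validation

The external check asks whether the synthetic wage behaves like real income
where it matters: in a health model. For each income measure the package
fits age/sex-adjusted logistic regressions of a binary poor-health
indicator on (a) the continuous measure scaled in units of £100 and (b) its
deciles, lowest decile as reference. Reported per term: odds ratio, 95%
Wald interval $\exp(\hat\beta \pm 1.96\,\mathrm{se})$, significance stars
(\*\*\* p<0.001, \*\* p<0.01, \* p<0.05), and the model's fit correlation —
the Pearson correlation between observed outcomes and fitted probabilities,
a measure suited to comparing non-nested models of the same outcome. No
small-sample corrections and no multiplicity adjustment are applied; these
are the conventions of epidemiological odds-ratio tables. Each model is
complete-case on its own variables, so sample sizes may differ across
measures. The binary coding of the health item is configurable
(`code_poor_health()`), since surveys word and scale the question
differently.

Logistic estimation goes through `stats::glm` (IRLS); the package adds
separation and rank-deficiency detection with explicit errors rather than
silently returning diverged coefficients.

## The synthetic data generator

Restricted-access survey data cannot ship with a package, so `sim_config()`
/ `simulate_study()` generate microdata with the statistical structure the
method assumes: log-normal wages with group effects at both classification
tiers, uniform ages within sex-specific working-age ranges, a survey-year
CPI drift (so preprocessing has real deflation work), multiplicative
log-normal "transitory" noise separating reported income from the
medium-term wage, and a latent-logit health outcome declining in the true
wage.

Default magnitudes were chosen once to be realistic for weekly pay in a
large national labour-force survey: fixed effects `beta0 = 5.1`,
`beta_age = 0.005`, `beta_male = 0.27`; group-effect SDs 0.37 (minor
intercept), 0 (minor slope — coarse-group age gradients add essentially
nothing once unit-level slopes exist), 0.32 (unit intercept), 0.0055 (unit
slope); residual SD 0.53. These put typical synthetic wages in the
£200–£350/week range at 2006-level prices with realistic occupational
dispersion. The health link (`health_alpha = -1.3`,
`health_gamma = -0.3` per £100, age slope 0.02) yields roughly 25%
prevalence and a clearly protective gradient. The transitory-noise SD of
0.3 makes reported income a visibly worse measure of the underlying wage
than the synthetic estimate — the scenario the method is designed for.

Each generator stage draws from its own seed sub-stream (seed + 1:
classification; + 2: group effects; + 3: master individuals; + 4: health
survey), so enlarging a later stage never perturbs earlier draws, and every
dataset is a pure function of the configuration.

What the generator does *not* emulate: real occupational wage
distributions calibrated to any actual survey, household structure and
income equivalisation, survey design weights, item non-response patterns,
or question-wording effects on self-rated health. The categorical
`sep_class` covariate is a synthetic stand-in (a binning of the minor-group
wage effect) for social-class or area-deprivation adjustment variables, and
is labelled as such. Passing tests therefore demonstrate that the
machinery is correct and that the method behaves as designed *under its own
assumptions* — not that any particular published estimate is reproduced.

## Problem sizes and test design

The test suite verifies exact identities on small dense problems (the
blockwise likelihood against a full multivariate-normal evaluation at
$10^{-6}$; the EB solver against the joint mixed-model equations at
$10^{-8}$; the one-level shrinkage closed form exactly) and statistical
recovery at survey scale: ten replicates of the default 50,000-record,
80×4-group design, requiring mean fixed effects within two Monte-Carlo
standard errors and mean variance components within 15% relative error.
The per-replicate sampling coefficient of variation of an 80-group variance
component is about $\sqrt{2/80} \approx 16\%$, which is why recovery is
assessed on means across replicates rather than per replicate. An
independent mixed-model implementation (lme4) serves as a cross-check
oracle on moderate problems; it is never used in the package's own
computation. The null-coverage check for logistic Wald intervals uses 200
replicates of size 400 — small enough to run in seconds, large enough that
the binomial 3-standard-deviation band around 95% is ±4.6 points.

## Known limitations

* The outlier trim's covariate attenuation, discussed above.
* Retired and unemployed people have no current occupation; the method
  says nothing about them (no pension or welfare imputation).
* Predictions carry no individual uncertainty intervals; the EB machinery
  could provide them, but the downstream use (a covariate in health
  models) rarely consumes them.
* Crossed (non-nested) classification structures and heteroscedastic
  residuals are out of scope; the likelihood factorisation relies on
  nesting.
* Household-level aggregation of predicted wages is deliberately not
  provided.
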