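---
title: "Methods: Bayesian heterogeneous treatment effect analysis for two-arm trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian heterogeneous treatment effect analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`bayeshte` implements a secondary Bayesian analysis workflow for a two-arm
randomized trial with a binary endpoint, patterned on large ICU oxygenation
trials with a 90-day all-cause mortality outcome. The workflow has three
statistical layers:

1. an **adjusted primary model** of the overall treatment effect,
2. **hierarchical subgroup models** that partially pool treatment effects
   across quintile-based subgroups of a baseline severity marker, and
3. **continuous interaction models** that put the same baseline marker into
   the linear predictor together with a treatment-by-marker product term.

Because patient-level data from such trials are confidential, the package
carries a first-class synthetic trial generator so that every stage is
testable end to end, and so that the sampler's calibration can be verified
against ground truth by simulation.

# Models

All three models are Bayesian logistic regressions. Writing $T_i \in \{0,1\}$
for allocation to the lower oxygenation target and $u_{s(i)}$ for the
intercept of patient $i$'s site:

**Primary.**
$$\operatorname{logit} P(\text{death}_i) = \alpha + \beta T_i +
\gamma_1\,\text{COPD}_i + \gamma_2\,\text{HAEM}_i + u_{s(i)}, \qquad
u_s \sim N(0, \sigma_{site}^2).$$

The adjustment set is the trial's randomization stratification variables
(chronic obstructive pulmonary disease, haematological malignancy, site).
Site enters as a partially pooled varying intercept rather than fixed
effects: with several dozen sites of very different sizes, fixed site
effects are fragile, and a half-normal prior on $\sigma_{site}$ keeps the
model proper when sites are sparse.

**Hierarchical subgroups.** For a subgrouping scheme $g(i) \in 1..5$,
$$\operatorname{logit} P = \alpha + a_{g(i)} + (\beta + b_{g(i)}) T_i +
\gamma_1\,\text{COPD} + \gamma_2\,\text{HAEM} + u_{s(i)},$$
with $a_g \sim N(0,\sigma_a)$ and $b_g \sim N(0,\sigma_b)$. The per-subgroup
treatment log-OR is $\beta + b_g$; partial pooling shrinks noisy subgroup
estimates toward the overall effect, with the amount of shrinkage learned
from the data through $\sigma_b$. Whether the original analysis also pooled
subgroup *intercepts* is not documented; both terms are included here
because subgroups of a severity marker plainly differ in baseline risk, and
`subgroup_intercepts = FALSE` disables $a_g$ for sensitivity analyses.

**Continuous interaction.** For a baseline covariate $x$,
$$\operatorname{logit} P = \alpha + \beta T + \delta x + \eta\,(T x) +
\gamma_1\,\text{COPD} + \gamma_2\,\text{HAEM} \,[+\, \gamma_3\,\text{OPEN}]
+ u_{s(i)},$$
linear on the log-OR scale by design (no splines — deliberately, to limit
the flexibility of a hypothesis-generating analysis). The open-system
adjustment $\gamma_3$ is added exactly when $x$ is the PaO2:FiO2 ratio,
because the measured ratio depends on the oxygen supplementation system.
$\exp(\eta)$ is the interaction OR per unit of $x$; `interaction_summary()`
reports $P(\eta < 0)$ and $P(\eta > 0)$ and the conditional-effect curve.

## Priors

The treatment log-OR prior is one of three families, all normal on the
log-OR scale (`prior_spec`):

* **weak** — $N(0, 1)$: centred on no effect, 95% of mass on ORs in
  $[0.14, 7.10]$, wide enough that trial data of a few thousand patients
  dominate the posterior.
* **sceptic** — $N(0, \sigma_s)$ with default $\sigma_s = 0.355$, putting
  95% of prior mass on ORs in about $[0.50, 2.01]$. The source protocol's
  exact value is not public; this is the conventional "sceptical of
  large effects" calibration and is overridable.
* **evidence** — the predictive distribution
  $N(\hat\mu, \sqrt{se(\hat\mu)^2 + \hat\tau^2})$ from a DerSimonian–Laird
  random-effects meta-analysis of previous trials' 2×2 tables. Using the
  predictive rather than the pooled-mean distribution transfers
  between-study heterogeneity into prior width, which is what an
  "evidence-based" sensitivity analysis intends. The packaged study table
  is synthetic and illustrative (clearly marked as such); users supply
  real trial counts.

Nuisance priors are weakly informative: $N(0, 2.5)$ on the intercept,
$N(0,1)$ on binary and standardized continuous coefficients, half-normal
$(0,1)$ on $\sigma_{site}$ and half-normal $(0, 0.5)$ on $\sigma_a$,
$\sigma_b$. The tighter hyperprior scale for subgroup terms encodes that
five exchangeable subgroups rarely support log-OR spreads beyond $\pm 1$;
all scales are `model_spec()` arguments.

## Posterior standardization

Event probabilities, RRs, RDs and ORs are computed **per posterior draw**
at a fixed covariate profile: every adjustment variable at its most common
value (ties toward the reference level; the modal site's own intercept
draw is used, applying the "most common value" convention literally to
site). For each draw, $p_T = \operatorname{logit}^{-1}(\text{linear
predictor at } T)$, then $RR = p_1/p_0$, $RD = p_1 - p_0$, and the OR
identity — so the per-draw algebra is exact by construction, and medians
with percentile 2.5/97.5 bounds summarize each quantity. Threshold
probabilities are empirical draw fractions $P(RR < c)$; equality, a
measure-zero event for continuous posteriors, counts with the lower side.
The default threshold grids (RR: 0.67, 0.80, 0.90, 1.00, 1.11, 1.25, 1.50;
RD: −5, −2, 0, +2, +5 percentage points) bracket the 20% relative
reduction such trials are typically powered for; the full pre-specified
protocol list is not public, so the grids are configurable.
Population-average (marginal) standardization is deliberately out of
scope: the modal-profile convention is the one being emulated.

# Sampler

Models are fitted by the package's own adaptive Hamiltonian Monte Carlo
backend (C++ via Rcpp):

* leapfrog integration with a trajectory length jittered uniformly on
  $1..L_{max}$ ($L_{max} = 20$ by default) to avoid periodicity;
* dual-averaging step-size adaptation toward a 0.8 acceptance statistic;
* diagonal mass-matrix estimation in two warm-up windows (25–55% and
  55–90% of warm-up), regularized toward unity, with the step size
  re-adapted after each update;
* non-centered parameterization of every random-effect block
  ($u = \sigma z$, $z \sim N(0,1)$, $\sigma$ sampled on the log scale with
  a half-normal prior), which removes the funnel geometry that plagues
  centered hierarchical logistic models;
* a divergence is recorded when the Hamiltonian error along a post-warm-up
  trajectory exceeds 1000 or becomes non-finite.

Chains run sequentially from R's RNG, so a single `seed` makes the entire
draw matrix reproducible. The default sampler configuration is 4 chains
with 5000 warm-up and 5000 post-warm-up draws per chain — 20 000 recorded
draws; tests and examples use reduced counts.

Correctness of the sampler is established three ways in the test suite:
against a dense 4-dimensional grid-quadrature oracle on a 40-patient toy
model; against an independent Gibbs sampler (JAGS) on a small hierarchical
model; and by simulation-based calibration — with data generated from the
fitted model and the true effect drawn from the prior, 95% credible
intervals must cover the truth at close to nominal rate with negligible
average bias.

## Diagnostics

`diagnostics()` reports rank-normalized split R-hat (the larger of the
bulk and folded statistics), bulk ESS (rank-normalized draws) and tail ESS
(the smaller ESS of the 5%/95% quantile indicators), using FFT
autocovariances truncated by Geyer's initial monotone sequence. The
verdict is *acceptable* exactly when max R-hat < 1.01 and no divergences
occurred; an unacceptable verdict is flagged, never fatal. With a single
chain, R-hat is reported as undefined.

# Quintile subgrouping with ties

Five subgroups per baseline variable target the 20/40/60/80th
percentiles, under the hard constraint that patients sharing an identical
value can never be separated. Heavy ties make naive percentile cuts
misbehave — repeated breakpoints produce empty groups and grossly unequal
sizes — so the scheme is defined as the optimum of an explicit criterion:
among all ordered partitions of the distinct values into five consecutive
runs, choose the one minimizing $\sum_g (G n_g - N)^2$ (an integer-exact
rescaling of squared deviations from $N/G$), breaking ties toward the
lexicographically smallest group boundaries. A dynamic program over the
distinct-value blocks finds the exact optimum; the test suite verifies it
against exhaustive enumeration on all short tied vectors. For untied data
this reproduces plain quintiles. Zero-inflated exposures (norepinephrine
dose) put all exact zeros into the first group and split the positive
values into quartiles, keeping five groups in total. At prediction time,
values are assigned by comparison with the inclusive group upper bounds
(boundary values fall to the lower group); out-of-range values go to the
nearest boundary group with a warning.

# Synthetic trial generator

`generator_config()` defaults emulate the printed baseline table of the
target cohort (n = 2888, 35 sites): marginal probabilities for COPD
(0.195), haematological malignancy (0.058), open oxygen system (0.286)
and any vasopressor use (0.547); log-normal lactate, PaO2:FiO2 and
norepinephrine-user dose moment-matched to the printed medians and IQRs
(e.g. lactate: meanlog $=\log 1.8$, sdlog 0.79 reproduces 1.8 [1.1–3.2]
mM); and a beta-binomial SOFA score on 0–24 with mean 8 and intraclass
dispersion 0.068, matched to median 8, IQR 5–10 — a plain binomial is too
concentrated to reach the printed IQR. The outcome follows the logistic
model above with configurable true effects; the default baseline logit
(−1.36) is chosen analytically so that marginal mortality lands near
42–43%. Allocation is 1:1 by permuted blocks of four within site × COPD ×
haematological-malignancy strata, so arm counts differ by at most one per
stratum. Missingness defaults mirror the printed footnote rates (about
3%, 0.4% and 0.7% for SOFA, PaO2:FiO2 and lactate) and only those three
variables can be masked.

What the generator does *not* emulate: covariates are mutually independent
(the true joint dependence of SOFA, lactate, norepinephrine dose and
PaO2:FiO2 is unknown and unpublished), site sizes are uniform, and there
is no longitudinal structure. Passing tests therefore demonstrate the
correctness and calibration of the *machinery* under the stated
generative assumptions — not that any particular real-data estimate is
reproduced, which would require the confidential patient-level data.

# Verification design choices

Several test-suite designs deserve explanation:

* **Coverage study.** 200 trials of n = 2888 are generated *from the
  fitted model's own structure* (treatment effect drawn from the weak
  prior; covariate effects only on the adjusted variables), the standard
  self-consistency design: only then is 95% coverage of the conditional
  log-OR the mathematically expected behaviour. Under the richer default
  generator, non-collapsibility of the logistic model makes the marginal
  and conditional effects differ — a property of the estimand, not a
  sampler defect.
* **Null-interaction calibration.** For a single null dataset the
  posterior probability of a positive interaction is itself approximately
  Uniform(0,1) — a single-seed check would be a coin flip. The test
  therefore averages $P(\text{interaction OR} > 1)$ over 20 independent
  null trials of n = 20 000 and requires the mean to sit near 1/2.
* **Shrinkage ordering.** With partially pooled subgroup *intercepts*,
  separately fitted per-subgroup models (each with its own free
  intercept) are not a like-for-like no-pooling comparator: intercept
  shrinkage redistributes fit between $a_g$ and $b_g$, and the
  hierarchical estimate can legitimately fall outside the interval they
  define. The betweenness property is therefore verified across three
  fits of the *same* model that differ only in the pooling scale
  ($\sigma_b$ hyperprior scale $10^{-3}$, 0.5, 25 — complete pooling,
  default, effectively none), with a 0.01 log-OR slack for Monte Carlo
  error.
* **Problem sizes.** Tests run with 2 chains and a few hundred draws per
  fit; the full 4 × (5000 + 5000) configuration is exercised once on a
  small trial to verify that exactly 20 000 draws are recorded in the
  persisted files. These sizes are the package's choice of a thorough but
  proportionate verification budget.

# Degenerate inputs and numerical notes

* An empty dataset is legal in `fit_primary()`: the posterior reproduces
  the prior (this is itself a test).
* A single site (or none) drops the site block; the intercept absorbs it.
* Constant interaction covariates are rejected (unidentifiable η).
* Continuous covariates are standardized internally for sampler geometry;
  reported draws are back-transformed so `alpha + beta T + delta x +
  eta T x` reads in original units, with `beta` the treatment log-OR at
  x = 0. $P(\eta > 0)$ is invariant to this rescaling.
* The 5% missingness gate compares integer counts (`20 * n_miss >= n`),
  so the boundary is exact: 4.9% proceeds as complete-case, 5.0% aborts
  with a pointer to multiple imputation, which is deliberately out of
  scope.
* The DerSimonian–Laird estimator applies the 0.5 continuity correction
  to all four cells of any table with a zero cell, uses
  $\tau^2 = \max\{0, (Q - (k-1))/(\sum w - \sum w^2/\sum w)\}$, and with a
  single study fixes $\tau^2 = 0$.

# Limitations

The package emulates a *class* of analyses; it does not reproduce any
trial's confidential data, and its printed real-data estimates cannot be
recovered here. Multiple imputation, sequential/interim analyses,
frequentist replication, spline interactions and model comparison
(LOO/WAIC) are out of scope. The sceptic prior SD and the evidence-prior
study list are explicit, overridable stand-ins for protocol values that
are not public.
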