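# bayeshte

Bayesian heterogeneous-treatment-effect (HTE) analysis for two-arm
randomized trials with a binary outcome, patterned on secondary analyses
of large ICU oxygenation trials with a 90-day mortality endpoint.

Clinical trials usually report one average treatment effect, but the
clinically urgent question is often *for whom* the treatment helps or
harms. `bayeshte` is for trial statisticians and intensive-care
researchers who want the full probabilistic workflow for that question:

* **adjusted Bayesian logistic regression** for the overall effect:
  `logit P(death) = α + β·T + γ₁·COPD + γ₂·HAEM + u_site`, with partially
  pooled site intercepts and a choice of three priors on the treatment
  log-OR — weakly informative `N(0,1)` (95% of prior mass on ORs
  0.14–7.10), sceptic `N(0, 0.355)`, or an evidence-based prior built from
  a DerSimonian–Laird random-effects meta-analysis of previous trials
  (predictive distribution `N(μ̂, √(se² + τ²))`);
* **hierarchical subgroup models** over tie-respecting quintile subgroups
  of a baseline severity marker (SOFA score, lactate, norepinephrine dose,
  PaO2:FiO2 ratio), with partial pooling
  `logit P = α + a_g + (β + b_g)·T + …` shrinking noisy subgroup effects
  toward the overall effect;
* **continuous interaction models** `… + δ·x + η·(T·x)` with the
  interaction OR per unit, directional probabilities P(OR<1)/P(OR>1), and
  conditional-effect curves;
* **posterior standardization**: per-draw adjusted event probabilities at
  the most common covariate profile, giving RR/RD/OR medians with
  percentile 95% credible intervals and threshold probabilities such as
  P(RR < 0.80);
* a built-in adaptive **HMC sampler** (Rcpp) with divergence counts, and
  diagnostics (rank-normalized split R-hat, bulk/tail ESS);
* a **synthetic trial generator** emulating a 2888-patient, 35-site
  cohort (stratified permuted-block 1:1 allocation, moment-matched
  baseline distributions, configurable true effects and missingness) so
  the whole pipeline is testable without confidential patient data.

## Worked example

```r
library(bayeshte)

# synthesize a trial emulating the target cohort, with a null true effect
ds <- generate_trial(generator_config(seed = 1))
ds
#> <trial_dataset> 2888 patients, 35 sites
#>   arms: 1448 lower / 1440 higher; deaths: 1193 (41.3%)

# primary adjusted analysis under the weakly informative prior
fit <- fit_primary(ds, model_spec("primary", chains = 4,
                                  warmup = 500, draws = 1000, seed = 2))
prof <- most_common_profile(ds, fit)
effect_summary(standardized_event_probs(fit, prof))
#> <effect_summary> 4000 draws
#>   P(event | lower):  40.1 (95% CrI: 31.7-48.8)%
#>   P(event | higher): 41.9 (95% CrI: 33.6-50.8)%
#>   RR: 0.95 (95% CrI: 0.87-1.04)   RD: -1.9 (95% CrI: -5.6-1.6) pp   OR: 0.92 (95% CrI: 0.79-1.07)
#>   P(RR < 1.00) = 0.849
```

The two event probabilities are the adjusted 90-day mortality risks in
the lower- and higher-target arms at the modal covariate profile; RR < 1
favours the lower target. Here the generator's true effect is zero, and
the posterior correctly concentrates near RR 1 — the residual deviation
is the trial's own sampling noise, spanned by the credible interval.

Continuous interaction with baseline norepinephrine dose:

```r
ifit <- fit_continuous_interaction(ds, "norepi_dose",
                                   model_spec("interaction", chains = 4,
                                              warmup = 500, draws = 1000, seed = 3))
interaction_summary(ifit, most_common_profile(ds, ifit))
#> <interaction_summary 'norepi_dose'> OR per unit 1.259 (95% CrI: 0.812-1.969)
#>   P(OR < 1) = 0.149   P(OR > 1) = 0.851
```

An end-to-end run (trial table, draws, diagnostics, effect tables,
figures, JSON manifest) is one call:

```r
bundle <- run_analysis(run_config(input = generator_config(seed = 1),
                                  prior = "weak", out_dir = "results_run"))
```

A thin command-line wrapper lives at `inst/scripts/bayeshte-cli.R`
(subcommands `simulate` and `run`).

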