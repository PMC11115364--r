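---
title: "Methods: models, estimation and simulation design in riskforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimation and simulation design in riskforage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette documents the modelling and numerical choices in `riskforage`.
Code chunks are illustrative and not evaluated when the vignette is built, so
the package remains fast to install; every claim below is enforced by the
test suite instead.

## 1. Task design

Each trial offers a gamble (`m` points with probability `p`) against a sure
10 points. `block_design()` builds one block:

* **Switch designs** (groups `PR`, `RP`): 66 trials per block — a full
  11 × 5 grid of magnitudes `m ∈ {15, 20, …, 65}` crossed with the five
  environment probabilities, plus 8 dominated catch trials (`m = 10`, the
  gamble can never beat the sure option, so the normative choice is reject)
  and 3 dominant catch trials (`p = 1`, `m > 10`, normative choice accept).
  Two blocks give 132 trials.
* **Intermediate designs** (groups `IPI`, `IRI`): 39 trials per block —
  an 11 × 3 grid plus 3 + 3 catch trials, over four blocks (144 trials).

Environments differ only in the probability support: poor
`{0.2, …, 0.6}` (mean 0.4), intermediate `{0.3, …, 0.7}` (mean 0.5), rich
`{0.4, …, 0.8}` (mean 0.6). The *analyzed* subset — used by every
downstream statistic — is the non-catch trials with `p ∈ {0.4, 0.5, 0.6}`
and `m > 10`, i.e. the 33 gambles per block common to all environments.
Comparing acceptance on this identical choice set across environments is the
core design idea: any difference must come from context, not from the
gambles themselves.

## 2. Decision models

`model_spec()` defines three utility families; all share a sigmoid choice
rule `P(accept) = logistic(β · (U(gamble) − U(sure)))` with inverse
temperature β > 0, and an optional approach-avoidance asymmetry η that tilts
the sigmoid's midpoint.

* **Risk-return** (`"risk_return"`): `U = mp − α·m²·p(1−p)`, mean minus
  α times variance. α > 0 is risk aversion; α is the parameter tracked by
  the state-space model.
* **Multiplicative prospect theory** (`"multiplicative"`):
  `U = m^λ · π(p)` with a Prelec probability weighting function
  `π(p) = exp(−(−log p)^γ)`; `include_lambda` / `include_gamma` toggle the
  curvature and weighting components.
* **Additive** (`"additive"`): `U = (1 − w_p)·m^λ / 65^λ + w_p·π(p)`, a
  weighted sum of normalized magnitude and weighted-probability utilities.

`simulate_choices()` plays a parameterized agent through a group schedule,
producing the same trial-table format as real data, including catch trials
and resolved outcomes.

## 3. Fitness simulations and the normative benchmark

`fitness_curves()` asks which risk attitude an agent *should* have. An agent
with risk-return parameter α plays 60 trials in a stable environment and
survives if accumulated reward reaches a need threshold; the need labels are
operationalized as thresholds on the 60-trial sum: **high** = 850,
**moderate** = 1000, **low** (hardest) = 1150. Alongside simulated survival,
`expected_accumulated_reward()` gives the analytic deterministic-limit
expectation: a β → ∞ agent accepts exactly when `U > 10`, so per-trial
expected reward is `E[max over the policy]` summed over the environment's
gamble distribution. Under the expected-accumulated-reward objective the
optimum is α* = 0 (risk neutrality) in every environment × need cell —
`optimal_alpha()` breaks ties toward 0, then toward risk proneness. Under
the *survival* objective the optimum shifts risk-prone (α* < 0) in poor
environments at moderate need, which is the normative motivation for
environment-dependent risk preferences. `scripts/acceptance.R` recomputes
the analytic headline from scratch at runtime.

## 4. Synthetic cohort generator

`generate_cohort()` draws a population whose ground truth is attached as an
attribute (never inferable from the table itself). Defaults in
`cohort_config()`: baseline α ~ Normal(1.8e-2, 0.4e-2), β ~ Gamma(16, 80)
(mean 0.2); the *effective* α on each trial is shifted down by an
environment-richness effect (2e-2 scaled by the current mean probability's
deviation from 0.5), a past-environment carry-over (1e-2), and an
accumulated-reward effect (0.2e-2 per within-block z unit); a perseveration
term (weight 2 on the previous choice) enters the choice rule directly.
Responses are omitted at rate 0.003 ("missing"). On catch trials agents obey
the dominant/dominated structure except for a 2% lapse rate — a deliberate
deviation from idealized perfect catch behavior so that the exclusion
machinery has realistic work to do. An `inattentive_fraction` of
participants instead answers at chance throughout, which the
catch-error exclusion should detect.

## 5. Preprocessing and exclusions

`apply_exclusions()` applies four a priori criteria and returns both the
filtered table and a per-participant report: incomplete sessions, more than
10% non-response, a constant choice policy on analyzed trials, and more than
10% errors on catch trials. Descriptives operate on analyzed responded
trials: `pooled_acceptance()` (acceptance fraction by arbitrary grouping
columns), `participant_acceptance()`, `moving_average_acceptance()`
(centered window, truncated at edges), and `fit_acceptance_curve()`
(per-participant logistic acceptance vs. `m` and `p`).

## 6. Bootstrap inference

Hypothesis tests resample *participants* with replacement, preserving
within-participant dependence. The statistic is the difference in pooled
acceptance `D = q₁ − q₂`; the one-tailed p-value is the add-one-smoothed
tail `p = (1 + #{D_null − D > 0}) / (1 + B)` with the null built by
resampling from the pooled participant set. Two-tailed tests double the
smaller smoothed tail; `m_tests` applies a Bonferroni factor, capped at 1.
With Bonferroni correction across `m` tests, the attainable p-value floor is
`2m/(B+1)`, so B must be chosen large enough for the intended α level
(e.g. B = 999 for m = 8 at α = 0.05). A precomputed index-matrix path makes
repeated tests on the same table fast.

## 7. Hierarchical expectation-maximization

`fit_hierarchical()` fits a population prior over individual parameters by
EM with MAP inner fits:

* **E-step**: per participant, a two-start (warm start from the previous
  iteration plus a neutral start) bounded L-BFGS-B maximization of
  log-likelihood plus log-prior, with Laplace variances from a
  bound-respecting central-difference Hessian. L-BFGS-B can abort when its
  line search produces non-finite *parameters* at an active bound (the
  objective itself is guarded and always finite); failed starts are dropped
  and, if all starts fail, a Nelder-Mead fallback on the guarded objective
  (solutions clamped to the box) is used, so the EM never crashes on a
  pathological participant.
* **M-step**: moment-matching of the prior families — Normal for α,
  Gamma for positive parameters (β, λ, γ), Beta for unit-interval
  parameters — using MAP estimates plus Laplace variances, with a
  log-concavity floor (Gamma shape ≥ 1, Beta hyperparameters ≥ 1, means
  preserved) so the MAP objective stays well behaved.
* **Convergence**: relative change in the penalized objective below
  `em_config(tol = 1e-4)` (degenerate zero-variance populations self-tighten
  forever; a looser tolerance is then appropriate).

Model comparison uses the integrated BIC: `iBIC = −2 Σᵢ log p(dataᵢ |
prior) + k · log(n_obs)`, with the per-participant marginal estimated by
Monte Carlo over prior draws (seeded, so reproducible) and `k` the number of
prior hyperparameters. `compare_models()` ranks fits;
`parameter_hypothesis_tests()` runs Bonferroni-corrected Welch t-tests on
per-participant MAP estimates between two fits.

## 8. State-space particle filter

`run_filter()` tracks a latent group-level risk-aversiveness trajectory
αₜ through the analyzed trial sequence. The state follows a Cauchy random
walk (scale σ; heavy tails let the trajectory jump at environment
switches), and the observation model is the Bernoulli likelihood of all
participants' choices on trial t given αₜ and a shared β. Weights are
normalized in log space; resampling is systematic. `fixed_lag_smooth()`
implements fixed-lag smoothing (default lag 20) via a genealogy buffer —
each particle's ancestry is traced back L steps so the smoothed
distribution at t − L uses information up to t. `grid_search()` scores
(σ, β) pairs by filter log-likelihood; `recovery_experiment()` simulates a
known trajectory, refits on a default 12-point log-σ × 13-point β grid, and
reports plateau relative error and credible-interval coverage.

## 9. Trial-history regression

`build_regressors()` computes eight regressors per analyzed responded
trial: `ev` (= mp), `risk` (= m²p(1−p)), `dpc` (trial probability minus
the current environment's mean), `dpp` (current minus previous environment
mean; 0 in the first block), `prev_choice`, `prev_reward`, `prev_success`,
and `acc_reward` (accumulated reward, z-scored within participant first).
All are then z-scored pooled per experiment; the scaling constants are
stored so `simulate_from_fit()` can re-standardize history regressors
consistently (static regressors reuse pooled statistics; history regressors
are pseudo-standardized from per-group raw statistics so the closed
simulation loop never peeks at realized data). `fit_logistic()` wraps
maximum-likelihood logistic regression with BIC, separation detection,
optional participant-bootstrap confidence intervals, and an optional
glmnet L1 path; `vif()` reports variance-inflation factors (EV/Risk and the
reward lags are moderately collinear by construction, ~10, which is
expected and reported rather than hidden). `ablation_suite()` refits with
dropped terms or extra lags and can re-simulate from each variant.

## 10. I/O, validation and full reproduction

`validate_trial_table()` checks column presence and types, enumerated
values, per-participant trial contiguity, group/block consistency, and the
outcome rules (reject ⇒ 10; accept ⇒ 0 or the magnitude; missing ⇒ NA),
with row-indexed error messages. `read_trial_table()` /
`write_trial_table()` round-trip the canonical CSV. `reproduce_all()` runs
the entire pipeline end to end at `scale = "full"` or `"smoke"`, writing
14 artifact files; everything except the timing log is byte-identical given
the same seed.

## Numerical conventions

* All stochastic functions take explicit seeds and restore nothing global.
* Probabilities are compared with absolute tolerances (never `==` on
  `seq()` output).
* Likelihood and posterior evaluations are guarded against non-finite
  values (clamped log terms), so optimizers always see finite objectives.
* Problem sizes scale from unit-test (seconds) through `smoke` (minutes) to
  `full`/acceptance scale; defaults are chosen so the shipped test suite
  completes well within a half hour on one core.
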