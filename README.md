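# riskforage

Analysis pipeline for accept/reject gambling tasks in which the richness of
the reward environment changes across blocks, together with the foraging
fitness simulations that motivate environment-dependent risk preferences.

Participants repeatedly choose between a sure 10 points and a gamble paying
`m` points with probability `p`. The probability distribution of offered
gambles defines the environment: **poor** (`p` ∈ {0.2, …, 0.6}, mean 0.4),
**intermediate** (mean 0.5) or **rich** (`p` ∈ {0.4, …, 0.8}, mean 0.6).
Environments switch between blocks (groups `PR`, `RP`, `IPI`, `IRI`), and the
central empirical question is whether risk taking in an identical choice set
depends on the richness of the surrounding environment.

## What the package provides

| Module | Entry points |
|---|---|
| Task design | `block_design()`, `group_schedule()`, `environment_probabilities()` |
| Decision models | `model_spec()`, `utility_params()`, `choice_probability()`, `simulate_choices()` |
| Fitness simulations | `need_condition()`, `expected_accumulated_reward()`, `fitness_curves()`, `optimal_alpha()` |
| Synthetic cohort | `cohort_config()`, `generate_cohort()` (ground truth attached as an attribute) |
| Preprocessing | `apply_exclusions()`, `analyzed_choices()`, `pooled_acceptance()`, `participant_acceptance()`, `moving_average_acceptance()`, `fit_acceptance_curve()` |
| Bootstrap inference | `one_tailed_diff_test()`, `two_tailed_diff_test()`, `percentile_ci()` |
| Hierarchical EM | `fit_hierarchical()`, `ibic()`, `candidate_models()`, `compare_models()`, `parameter_hypothesis_tests()` |
| State-space model | `run_filter()`, `fixed_lag_smooth()`, `grid_search()`, `recovery_experiment()`, `simulate_from_trajectory()` |
| Trial-history regression | `build_regressors()`, `fit_logistic()`, `vif()`, `simulate_from_fit()`, `ablation_suite()` |
| I/O and reproduction | `read_trial_table()`, `write_trial_table()`, `validate_trial_table()`, `reproduce_all()` |

The decision models cover a risk-return family
(`U = mp − α·m²·p(1−p)`, so α > 0 is risk aversion), a multiplicative
prospect-theory family (`m^λ · π(p)` with a Prelec weighting function) and an
additive family, each with a sigmoid choice rule (inverse temperature β) and
an optional approach-avoidance asymmetry η.

## Worked example

```r
library(riskforage)

cfg    <- cohort_config(n_per_group = 20, inattentive_fraction = 0.1, seed = 42)
cohort <- generate_cohort(cfg)          # PR and RP groups, 132 trials each
excl   <- apply_exclusions(cohort)      # a priori exclusion criteria
sum(excl$report$kept)                   # 35 of 40 participants kept

pooled_acceptance(excl$table, by = c("group", "block_index", "environment"))
#>   group block_index environment n_accept n_choices         q
#> 1    PR           1        poor      379       593 0.6391231
#> 2    PR           2        rich      340       593 0.5733558
#> 3    RP           1        rich      270       558 0.4838710
#> 4    RP           2        poor      265       560 0.4732143

# Between-group contrast on the first block: the PR group (poor environment)
# accepts more than the RP group (rich environment) on identical choice sets.
one_tailed_diff_test(
  excl$table[excl$table$group == "PR" & excl$table$block_index == 1, ],
  excl$table[excl$table$group == "RP" & excl$table$block_index == 1, ],
  B = 9999, seed = 1)
#> <bootstrap_result> D = 0.1553, p = 0.0001 (B = 9999), 95% CI [0.0790, 0.2333]
```

From here, `fit_hierarchical(model_spec("risk_return"), excl$table,
environment = "poor")` fits the population model by expectation-maximization,
`ibic()` scores it for model comparison, and `run_filter()` tracks the latent
group-level risk-aversiveness trajectory trial by trial.

## License

MIT (see `LICENSE`).
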