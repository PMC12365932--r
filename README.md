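# distractlearn

Computational models of statistically learned distractor suppression in
visual search, with a hierarchical Bayesian fitting and model-comparison
pipeline that runs end to end on fully synthetic data.

## The scientific problem

In the additional-singleton paradigm, observers search six-item displays for
a shape-singleton target while, on half of the trials, one non-target is a
salient color singleton (the distractor). When the distractor occupies one
*high-probability (HP) location* on 66.67% of distractor-present trials,
observers learn to suppress that location: they are captured less (faster
RTs) when the distractor appears there, and slower to select targets that
land there. `distractlearn` asks *how* that learning works: is suppression
proportional to an accumulating count of distractor occurrences, driven by
reinforcement-learning prediction errors, or applied all-or-nothing to the
single most distractor-associated location?

The package is aimed at attention and cognitive-modeling researchers who
want to (a) generate exactly counterbalanced trial sequences with this
probability structure, (b) simulate and fit trial-level RT models on them,
and (c) quantify how reliably a hierarchical model comparison can tell the
candidate mechanisms apart.

## The models

All models predict RT (in seconds) on distractor-present trials with a
Gaussian GLM whose residual SD is profiled at its MLE,
σ̂ = √(RSS/n). Shared regressors are a global practice decay
exp(−b_global·(i−1)) over distractor-present trials i and a previous-trial
distractor-absent dummy. The learning mechanisms differ in the
location-level regressor:

| Model | Mechanism | Location regressor |
|---|---|---|
| 1 (4) | accumulator (+block reset) | pDist = 1 − exp(−b_distractor·count) |
| 2 (5) | Rescorla–Wagner (+reset) | pDist ← pDist + α(Dist − pDist), init 1/6 |
| 3 (6) | categorical (+reset) | 1 iff distractor at the argmax count (ties in) |
| 7 | priming only | previous-trial repetition + absence dummies |
| 8 (9) | accumulator, no global decay (+reset) | as Model 1 |

Models are fitted and compared with a hierarchical random-effects
procedure: per-subject MAP estimation under raw-space normal priors
(mean 0, variance 6.25), Laplace model evidence, responsibility-weighted
group updates, and a Dirichlet over model frequencies yielding exceedance
probabilities, the Bayesian omnibus risk (bor), and protected exceedance
probabilities pxp = xp·(1 − bor) + bor/K.

## Worked example

```r
library(distractlearn)

# A 17-subject synthetic group from the categorical model (Model 3) on the
# 8-block constant-probability design, 50 ms RT noise
spec <- default_group_spec(17)
ds   <- simulate_group(spec, exp1_design(seed = 11), noise = 50, seed = 5)

# Refit the generating model hierarchically
fit <- fit_hierarchical(3, ds$subjects, n_starts = 2, seed = 1)
round(fit$models$model_3$group_mean, 4)
#>          b_global    beta_intercept beta_global_decay  beta_categorical
#>           -4.0674            0.8846            0.0923           -0.0426
#>  beta_prev_absent
#>            0.0001
```

The recovered group means sit on the generating values: the intercept
(≈0.885 s vs 0.895 s generating), the global-decay coefficient (0.092 s),
and the negative categorical-suppression coefficient (−0.043 s vs −0.040 s)
— i.e. trials with the distractor at the most distractor-associated
location are ~40 ms faster. Comparing all four mechanisms on the same data:

```r
cmp <- fit_hierarchical(c(1, 2, 3, 7), ds$subjects, n_starts = 2,
                        warm_starts = 0, seed = 1)
cmp
#> Hierarchical model comparison (4 models, 17 subjects)
#>  model frequency exceedance   pxp
#>      1     0.268      0.101 0.130
#>      2     0.136      0.009 0.055
#>      3     0.501      0.887 0.765
#>      7     0.095      0.003 0.050
#> bor = 0.1912; NOT converged in 50 iterations
```

The generating categorical model wins the comparison (highest exceedance
probability), with the accumulator model its closest mimic — exactly the
confusability structure these mechanisms are known for. `run_recovery()`
repeats this over many simulated datasets and tabulates a confusion matrix;
`run_pipeline()` chains design → simulate → fit → recover → summarize from
a single JSON config and seed.

## Package layout

- `R/task_design.R` — designs, sequence generation, validation, labeling
- `R/learning_models.R` — the nine models' regressors and the GLM likelihood
- `R/inference.R` — MAP + Laplace evidence, hierarchical fitting, pxp/bor
- `R/synthetic_data.R` — group draws, RT simulation with noise and clipping
- `R/recovery.R` — model-recovery experiments and confusion matrices
- `R/behavior.R` — condition means, gradients, priming and binning summaries
- `R/pipeline.R` — JSON config handling and the end-to-end pipeline
- `vignettes/modeling-distractor-suppression.Rmd` — methods and design notes
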