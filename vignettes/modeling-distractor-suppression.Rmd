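---
title: "Modeling statistically learned distractor suppression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling statistically learned distractor suppression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(distractlearn)
```

This vignette documents the models, the fitting machinery, and the design
decisions behind `distractlearn`, in the spirit of a methods section: what
is computed, under which assumptions, and where the genuinely open choices
were resolved.

## The paradigm and its probability structure

Six search locations sit on a ring. Every trial contains a shape-singleton
target; on 50% of trials one non-target is a salient color singleton (the
distractor). Given a distractor, it occupies the high-probability (HP)
location with probability 2/3; the remaining presentations are split
equally over the five low-probability (LP) locations. Within every block
of 60 trials the counts are exact, not expected values: 30 present trials,
20 HP, 2 per LP location, and the target at every location exactly 10
times. Because the target can never share the HP location with an HP
distractor, half of the LP-distractor trials place the target at the HP
location in compensation; `validate_sequence()` checks all of these
identities per block.

Two schedules are supported: *constant* (one HP location throughout) and
*changing* (the HP location changes every `change_interval_trials` trials —
180 in the canonical 18-block design — with each location serving exactly
once, in a seeded random order).

Decisions that the paradigm description leaves open, and how this package
resolves them:

- **LP distractor → target mapping.** The counterbalancing requires that
  the five "target not at HP" LP trials per block place the target once at
  each LP location, with target ≠ distractor. Any derangement of the LP
  locations satisfies this. The `"predefined"` mode uses a fixed shift by
  two positions within the cyclically ordered LP locations (the same map
  every block); the `"random"` mode draws a fresh seeded uniform
  derangement per block. An unconstrained uniform draw of the target would
  break the exact per-block target balance, so the randomized mode
  randomizes *within* the class of count-preserving maps.
- **Trial order** within a block is a seeded uniform shuffle of the
  quota-satisfying trial multiset; nothing beyond the quotas constrains it.
- **Distances** are minimal circular steps on the ring (0 = HP, 3 =
  opposite). Locations are indexed 0–5 clockwise.
- Fixation jitter and stimulus colors influence no modeled quantity;
  singleton color is stored (seeded 50/50) for completeness only.

## The trial-level GLM

All models predict RT in **seconds** on distractor-present trials with a
Gaussian GLM. Working in seconds keeps every coefficient on a comparable
scale so a single prior variance can serve all parameters. The residual SD
is profiled at its maximum-likelihood value on every evaluation,
$\hat\sigma = \sqrt{RSS/n}$, giving the closed form

$$LL = -\tfrac{n}{2}\,(1 + \ln 2\pi) - n \ln \hat\sigma .$$

The unit tests verify this equals a naive per-trial Gaussian log-density
sum to $10^{-10}$. A fit with all residuals exactly zero has no
maximum-likelihood $\hat\sigma$ and raises a degenerate-likelihood error.

**Inclusion rules.** Rows are distractor-present trials, excluding the
first trial of each block (its previous-trial context is undefined),
inaccurate trials, and trials with RT < 200 ms. The 2000 ms response
deadline bounds RTs from above. Accuracy summaries, by contrast, use all
trials. Two related choices deserve emphasis:

- **Learning states update on *all* distractor-present trials,** including
  ones excluded from the GLM rows. Exclusions are measurement filters, not
  experience filters: a subject still saw the excluded trial.
- **The global-decay index counts all distractor-present trials** and never
  resets across blocks; the block-resetting model variants reset only the
  location-level learning states.

**Standardization.** Continuous regressors — the global decay curve and the
graded distractor predictions — are z-scored per subject over the included
rows. Dummy and categorical columns stay 0/1 so their coefficients read
directly as RT differences in seconds. A numerically constant continuous
column (e.g. a decay rate near zero) is set to zeros rather than producing
NaNs; the coefficient then simply absorbs into the intercept's null space
and the optimizer keeps moving.

## The nine candidate models

| id | mechanism | location regressor | free parameters |
|----|-----------|--------------------|-----------------|
| 1  | accumulator | $1 - e^{-b_{distractor} c_{l}}$ | 6 |
| 2  | Rescorla–Wagner | $p_l \leftarrow p_l + \alpha(d_l - p_l)$ | 6 |
| 3  | categorical | 1 iff distractor at argmax count (ties included) | 5 |
| 4/5/6 | block-reset variants of 1/2/3 | as above | 6/6/5 |
| 7  | priming only | previous-trial repetition dummy | 5 |
| 8/9 | 1/4 without global decay | as Model 1 | 4 |

State-machine conventions, uniformly: the prediction used for trial $i$
reflects state through trial $i-1$ (the only causally coherent reading);
delta-rule predictions start at 0.16667 per location and update on
distractor-present trials only (so predictions never decay on absent
trials); the categorical regressor is computed from the raw counts —
parameter-free, because the argmax is invariant to any monotone transform —
and its all-tied initial state codes every location as 1. Counts are
reset to zero (predictions to 0.16667) at block starts in the resetting
variants.

Parameter transforms keep the hierarchical prior normal in an
unconstrained *raw* space: decay rates are `exp()`-transformed
(positivity), the learning rate passes through the logistic (unit
interval), and GLM coefficients are untouched. Models 8/9 drop both the
global-decay regressor and its rate, leaving 4 free parameters.

## Hierarchical fitting and model comparison

Subject-level fits are MAP estimates of the raw parameter vector under a
normal prior (mean 0, variance 6.25 per parameter initially), obtained by
multi-start BFGS — one start at the prior mean, the rest drawn from the
prior — with the objective floored at $-10^{20}$. Model evidence uses the
Laplace approximation
$\log p(y) \approx \log p(y,\theta^\ast) + \tfrac{d}{2}\log 2\pi -
\tfrac12 \log\det H$, with near-singular Hessians ridge-regularized (a
warning is logged).

The hierarchical loop alternates:

1. **E-step:** per-subject MAPs and evidences under each model's current
   group prior; responsibilities as the softmax of evidence plus the
   expected log model frequency $\psi(\alpha_k) - \psi(\sum\alpha)$.
2. **M-step:** Dirichlet counts $\alpha_k = 1 + \sum_n r_{nk}$ (prior count
   1 per model); group means as responsibility-weighted MAP means; group
   variances as responsibility-weighted second moments *including each
   subject's Laplace posterior variance* (which prevents variance
   collapse), floored at $10^{-6}$.

Convergence is declared when the summed data log evidence changes by less
than `tol` (default $10^{-4}$); otherwise the loop stops at
`max_iterations` (default 50, also the cap used in recovery runs) with a
non-convergence flag. After the first sweep, subject fits warm-start from
the previous MAP, and the data Hessian is reused whenever the MAP moved by
less than $5\times10^{-4}$ in every coordinate (the diagonal prior
contribution is refreshed exactly) — the numerical Hessian otherwise
dominates runtime.

Comparison outputs: exceedance probabilities by Monte Carlo over the
Dirichlet (default $10^6$ draws; the $K=2$ Beta-tail closed form serves as
an in-test cross-check), the Bayesian omnibus risk from the variational
free energy of the fitted frequency model against the exact evidence of
the equal-frequency null, and protected exceedance probabilities
$pxp_k = xp_k (1 - bor) + bor/K$. Recovery experiments score the winner by
the highest *exceedance* probability; exact ties (possible only
degenerately) break to the lowest model id with a warning.

**Hierarchical t-tests.** The reported `hierarchical_error` is
$\sqrt{v_k/(R_k+1)}$ — the group-level uncertainty of the mean, with $R_k$
the model's summed responsibility — and the t-statistic divides the group
mean by it. The degrees of freedom are supplied by the procedure as
$R_k + 1$: when one model absorbs all responsibility this equals the
number of subjects plus one, which is the convention this package adopts
for method-supplied (possibly non-integer) dof.

## The synthetic-data generator

`simulate_group()` draws per-subject raw parameter vectors from
$\mathcal{N}(\text{group mean}, \text{group SD}^2)$, builds each model's
design matrix exactly as the fitting pipeline does (same exclusions, same
per-subject z-scoring), adds Gaussian noise to the GLM mean, and clips RTs
to the 200–2000 ms response window. Accuracy labels are i.i.d.
Bernoulli(0.95) by default, matching the ~94–98% accuracies typical of
this paradigm; a template vector can be substituted. Distractor-absent
trials receive placeholder RTs (intercept plus the decay term) purely for
dataset realism — they never enter fitting.

Defaults for recovery studies come from `default_group_spec()`: the
categorical model's reference group parameters for the constant-probability
design (intercept 0.895 s, global-decay coefficient 0.092 s, categorical
coefficient −0.040 s, previous-absent coefficient −0.006 s, natural decay
rate 0.015), with the hierarchical spread set to the reported interval
half-widths and the decay rate mapped to the raw log scale by the delta
method (0.005/0.015). The low-noise condition fixes the RT noise SD at
50 ms; a per-subject mode assigns supplied SDs without replacement for
residual-matched noise.

What the generator deliberately does *not* emulate: sequential-sampling RT
shapes (RTs are Gaussian around the GLM mean, where real RT distributions
are right-skewed), lapses and post-error slowing, any coupling between
accuracy and the learning state, and real subjects' trial sequences or
accuracy label autocorrelation. Passing recovery tests therefore show that
the *fitting machinery* is correct and that the mechanisms are separable
at the stated noise level — not that real data are this well behaved.

## Problem sizes and numerical choices

The recovery experiments shipped in the tests and the acceptance script
use the study-scale conditions — 17 subjects × 480 trials per dataset, 10
replicate datasets, candidates {1, 2, 3, 7}, 50 ms noise, winner by
exceedance — with 2 fresh optimizer starts on the first sweep and
warm-start-only sweeps thereafter (`warm_starts = 0` in
`recovery_config()`), which keeps a full 10-dataset recovery around ten
minutes on one CPU. Exploratory fits in the examples use `n_starts = 2` as
well; raise `n_starts` (default 8 in `fit_subject_map()`) for production
fits of real data.

Other numerical conventions, collected: prediction-quartile binning
assigns tie values to the lower quartile and degenerates to a single
warned bin when all predictions are equal; `gradient_slope()` returns a
reasoned NA when a distance bin is empty; `last_hp_means()` excludes the
first HP epoch and applies only to changing schedules; JSON serialization
uses full floating-point precision so that write/read round trips are
exact; all randomness flows from explicit integer seeds (sequence
generation derives a per-subject seed from the design seed and subject id,
and the pipeline derives all stage seeds from one global seed) and never
disturbs the caller's RNG state.

## Known limitations

- The comparison machinery is a from-scratch implementation of the
  hierarchical random-effects scheme described above; constants such as
  the Dirichlet prior count, convergence tolerance, and restart counts are
  configuration, and other implementations of the same family may differ
  in those defaults.
- Gaussian RT likelihoods are assumed throughout; lognormal or
  shifted-Wald likelihoods, spatially graded (distance-weighted)
  suppression, and frequentist mixed-effects alternatives are out of
  scope.
- Omnibus ANOVAs and corrected post-hoc t-tests on the behavioral
  summaries are left to standard tools (`aov`, `t.test`, `p.adjust`); the
  behavior module emits the per-subject condition tables those tests
  consume.
- With all subjects' evidences equal across models, the omnibus risk is
  high and pxp approaches uniform — by design, pxp is conservative when
  frequencies are indistinguishable.
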