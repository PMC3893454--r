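---
title: "Simulating and analyzing the two-step task: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing the two-step task: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostepr)
```

## The task and the two controllers

The two-step sequential decision task dissociates two modes of
reinforcement learning. On each trial a first-stage choice between two
options leads probabilistically to one of two second-stage states — each
option leads to "its" state with probability 0.7 (a *common* transition)
and to the other with probability 0.3 (*rare*). A second choice in that
state is then rewarded or not according to option-specific reward
probabilities that drift across trials as bounded Gaussian random walks
(increment SD 0.025, reflected into [0.2, 0.8]). A session has 201 trials.

A *model-free* controller caches action values updated by reward
prediction errors: a reward makes the just-taken first-stage choice more
likely to be repeated, regardless of how the reward was reached. A
*model-based* controller plans through the transition structure: a reward
obtained after a rare transition makes it *more* attractive to switch,
because the other first-stage option reaches the rewarded state more
reliably. In 1-back stay/switch terms, model-free control appears as a
main effect of the previous reward on the probability of staying, and
model-based control as a reward-by-transition interaction.

## The hybrid agent

`run_session()` simulates a hybrid agent with parameters
`hybrid_params()`:

* model-free values are learned by SARSA(lambda):
  `delta1 = Q2(s2, c2) - Q1(c1)`, `Q1(c1) += alpha1 * delta1`;
  `delta2 = r - Q2(s2, c2)`, `Q2(s2, c2) += alpha2 * delta2`,
  `Q1(c1) += alpha1 * lam * delta2`;
* model-based stage-1 values are recomputed each trial by a one-step
  Bellman backup over the *true* transition matrix
  (`QMB(a) = 0.7 * max_b Q2(common(a), b) + 0.3 * max_b Q2(rare(a), b)`).
  The agent is given the true transition probabilities rather than having
  to learn them, because participants are explicitly instructed that the
  transition structure is fixed;
* first-stage choice is a softmax (inverse temperature `beta1`) over
  `w * QMB + (1 - w) * QMF + rho * [repeat of previous choice]`; `w` in
  [0, 1] is the model-based weight, `rho` a perseveration bonus;
* second-stage choice is a softmax over the visited state's cached values
  (`beta2`).

All values start at 0 (rewards are 0/1, so this is the symmetric,
uninformative origin). Default simulation parameters are
`alpha1 = alpha2 = 0.4`, `lam = 0.6`, `beta1 = beta2 = 5`, `rho = 0.2` —
mid-range values that produce the familiar hybrid stay/switch pattern.
Walk screening and the pure-controller signature checks use `rho = 0`, so
that a "purely model-free" agent is exactly that.

## Walk screening

Reward walks are not all equally usable: a walk in which one second-stage
option sits near the upper bound for a long stretch makes the optimal
strategy static, and the 1-back analysis then exhibits a
reward-by-transition interaction even for a purely model-free agent.
`screen_walk()` operationalizes "no spurious interaction" by simulating
`n_agents = 500` model-free agents (`w = 0` enforced) on the candidate
walk and accepting it only if (a) the 95% normal-approximation CI of the
mean interaction covers 0 and (b) the absolute mean interaction is below
0.05 in stay-probability units. The magnitude guard protects against a
tightly estimated but practically non-zero bias; the CI protects against
accepting on noise. The report records that the interaction was
quantified with stay-probability contrasts (not regression coefficients)
— both quantifications exist in the package and agree in sign for clearly
non-zero effects, but the table contrast is cheaper and scale-bounded.

## Stay/switch quantification

`lag_session()` pairs each trial with its predecessor (pairs touching a
missed trial are dropped — the simulator never generates misses, but the
data model carries the flag so that real and fixture data exercise the
same path). `stay_table()` averages staying within the 2x2 of previous
reward x previous transition, and `effect_indices()` extracts

* `mf_effect` — the average simple effect of reward,
  `mean_tr(p[r=1, tr] - p[r=0, tr])`;
* `mb_effect` — the double difference
  `(p[1, common] - p[1, rare]) - (p[0, common] - p[0, rare])`;
* `balance = mb_effect - mf_effect`.

These are the canonical main-effect and interaction contrasts of a 2x2
table; the numerical weights are a design choice (no standard exists),
and all downstream results use them consistently. Tables with an empty
cell are flagged invalid and refused by `effect_indices()` rather than
imputed — with 201 trials per session empty cells essentially never occur,
but very short synthetic sessions can produce them.

## The hierarchical logistic regression

`build_design()` codes the previous reward as -0.5/+0.5 and the previous
transition as +0.5 (common) / -0.5 (rare). Centered coding makes the
interaction orthogonal to the main effects and the intercept
interpretable as the grand mean stay log-odds. The 12 regressors are the
intercept, dummies for the two dlPFC stimulation sites (the vertex main
effect is absorbed in the intercept), and site-specific reward,
transition, and reward-by-transition terms, so exactly one regressor of
each triple is active on any row.

`fit_hier_logit()` fits the logistic mixed model with all 12 coefficients
as random effects over subjects, by Laplace-approximated marginal maximum
likelihood (`lme4::glmer`, `bobyqa`). The random-effect covariance is
*diagonal* (independent effects, the double-bar formula): a full 12x12
covariance has 78 parameters and is not identifiable from 25 subjects.
With `random_effects = FALSE` the same deviance machinery is evaluated
with all variances pinned at zero and only the fixed effects optimized,
which collapses to pooled ordinary logistic regression — the package's
degenerate-case check.

Site comparisons use 1-df Wald chi-square contrasts on the fixed effects
(`wald_contrast()`: `chi2 = (w'beta)^2 / (w'Vw)`), including the balance
contrasts `(interaction - reward)` between sites. The balance is
contrasted as a coefficient difference on the fitted model, not by
refitting a reparameterized model; with a linear contrast the two are
equivalent for the estimate and its Wald test. No multiplicity correction
is applied; contrasts are reported at nominal p.

## Correlations and the paired permutation test

Per-subject balance indices are correlated with working-memory capacity K
(Pearson). Differences between the WM correlation in two within-subject
conditions are tested by `perm_corr_diff()`: under the null the condition
labels are exchangeable within subject, so each subject's pair of balance
values is independently swapped with probability 1/2 per permutation,
keeping the WM covariate fixed — this respects the repeated-measures
pairing. The two-sided p-value uses the add-one estimator
`(1 + #{|null| >= |obs|}) / (n_perm + 1)`, so `p >= 1/(n_perm + 1)` and
exact ties count against rejection. Working-memory capacity is
`cowan_k()`: `K = set_size * (hit - false alarm)`, clipped below at 0 —
the single-probe change-detection formula, appropriate for a task probing
one location of a five-item array.

## The synthetic cohort generator

`generate_cohort()` emulates a within-subject, three-condition study of
25 subjects x 201 trials: each subject receives a working-memory capacity
`K ~ N(3, 1.2)` clipped to [0, 5] and a baseline model-based weight
`w ~ N(0.6, 0.15)` clipped to [0, 1]; right-dlPFC stimulation lowers `w`
by 0.3, left-dlPFC stimulation lowers it by
`max(0, 0.8 * (1 - K/5))` — i.e. a subject with no working-memory
capacity loses nearly all model-based control, high-WM subjects retain it
— and vertex leaves `w` at baseline. Three walks are pre-screened with 500 model-free agents each
and assigned to each subject's sessions in random order; condition order
is counterbalanced (all six permutations cycled over subjects 1-24, a
random order for the 25th).

The effect sizes are free parameters of the generator, not estimates from
any dataset: the published analyses report coefficients only as figures
and p-values, so the generator's defaults were chosen by pilot simulation
so that the 25-subject design has moderate power for the qualitative
pattern (a clearly negative right-vs-vertex interaction contrast, a
positive WM-balance correlation under left dlPFC, none at vertex). The
single-session interaction index is a noisy measurement (its Monte-Carlo
SD at 201 trials is roughly 0.13 in stay-probability units, comparable to
the largest weight-induced signal a plausible population can carry), so
the generating weights must spread widely for per-subject indices to
order subjects reliably; the baseline `w` mean/SD (0.6/0.15) describe a
mostly hybrid population and keep the left-condition weights clear of the
`[0, 1]` clipping that would otherwise flatten the WM coupling.
The generator couples K *directly* to the left-condition `w` reduction;
it deliberately does not model any mediating mechanism.

What the generator does *not* emulate: missed responses and response
times, practice blocks and in-task breaks, session-order (learning)
effects, payment, and any drift in agent parameters across sessions.
Passing end-to-end tests therefore show that the analysis recovers the
structure *this* generative model plants at realistic scale — not that
the analysis is robust to the further idiosyncrasies of human data.

## Numerical choices and limitations

* Walk boundaries are *reflecting* (excess beyond a bound is folded
  back): truncation would pile probability mass at the bounds and distort
  the increment distribution near them. Initial values are uniform within
  the bounds unless fixed.
* The transition mapping is fixed (choice k leads commonly to state k);
  any bijection is behaviorally equivalent. Left/right screen positions
  are not modeled; choices are stimulus-indexed.
* Softmax probabilities are computed from value differences, so they are
  numerically stable for any finite inverse temperature.
* `fit_hier_logit()` reports `converged = FALSE` (and refuses contrasts)
  rather than returning silent estimates when the optimizer flags a
  problem.
* Wald contrasts rely on the asymptotic normality of the fixed effects;
  with very few subjects their p-values can be liberal. Calibration was
  verified by simulation at 8-12 subjects and holds there; far smaller
  cohorts are untested.
* Test and verification problem sizes (e.g. 500 agents per signature
  check, 200 replicate fits at 12 subjects x 40 trials for the null
  calibration, 10 replicate cohorts for end-to-end recovery) were chosen
  to keep the full verification suite at desk scale while leaving
  Monte-Carlo error well below the margins being asserted.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
study <- generate_cohort(cohort_spec(seed = 1))
res <- analyze_study(study$sessions, study$wm, n_perm = 10000)

res$contrasts      # 9 site contrasts (reward / interaction / balance)
res$correlations   # WM x balance per condition
res$perm_tests     # pairwise permutation tests
```

The recovery report (`recovery_report()`) adds the comparison against the
generating truth: the sign of the right-vs-vertex interaction contrast,
the WM-balance correlations, and the rank correlation between each
session's generating `w` and its estimated interaction index.
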