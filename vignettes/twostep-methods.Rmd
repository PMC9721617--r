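---
title: "Modelling model-based versus model-free control in the deterministic two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling model-based versus model-free control in the deterministic two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the scientific question

`twostepRL` implements a complete analysis pipeline for a deterministic
variant of the two-step decision task. On every trial the participant starts
in one of two first-stage states, each showing a pair of spaceships. Each
spaceship flies *deterministically* to one of two planets, where an alien
pays out integer points; the mapping from spaceships to planets is constant
throughout the experiment, but the points paid by each planet drift over
trials as independent bounded Gaussian random walks. Because both first-stage
states reach the same two planets, a participant who uses the task structure
("model-based" control) can transfer what they learned after choosing
spaceship A to spaceship C that flies to the same planet, even though A and C
never appear together. A participant who repeats whatever spaceship was
rewarded ("model-free" or habitual control) cannot.

The central quantity of interest is the weight `omega` that mixes these two
controllers, and how a pharmacological treatment administered between two
sessions shifts `omega` (and the other decision parameters) relative to
placebo. Everything in the package — the task simulator, the choice models,
the hierarchical estimation of treatment effects, the stay-behaviour
regression, and model comparison — exists to answer that question on either
real trial tables or fully synthetic cohorts.

## Task environment

`task_config()` fixes the environment: 200 trials per session by default,
reward bounds `[-4, 5]`, drift rates (the SD of the latent walk's Gaussian
increments) 0.5, 1 and 2, and a deterministic 2x2 transition map. Three
design choices deserve comment because the task description leaves them
open:

* **Drift schedule.** The three drift rates are laid out over contiguous,
  equal-length blocks in the order given. The exact published block
  structure is not available; contiguous blocks preserve the intended
  property that difficulty varies within a session while keeping the
  schedule a transparent, inspectable vector (`drift_schedule`) that users
  can replace.
* **Bouncing boundaries.** Excursions of the latent walk beyond a bound are
  reflected (`x -> 2*bound - x`, applied iteratively), and the delivered
  reward is the latent value rounded to the nearest integer. Reflection
  preserves the walk's local variance near the bounds, where clipping would
  pile mass onto the boundary values.
* **First-stage sequence.** A seeded Markov chain repeats the previous
  first-stage state with probability `p_same_state` (default 0.5), giving
  equal state frequencies and, on average, half "same-state" and half
  "different-state" transitions — the contrast the stay-behaviour analysis
  relies on.

Missed or timed-out responses are not modelled: the simulator never produces
them, and `read_trials()` drops incomplete rows with a reported count.

## The three choice models

All models share the same decision rule. The value of action `a` in
first-stage state `s` is a mixture

```
Q(a, s) = omega * QMB(a, s) + (1 - omega) * QMF(a, s)
```

mapped to choice probabilities by a softmax with inverse temperature `eta`.
The model-based value is always the value of the planet the action leads to,
`QMB(a, s) = Q2(T[s, a])`, so an outcome on one planet immediately updates
the model-based value of *both* spaceships flying there.

* **M1 (last-outcome learner).** Because rewards follow random walks, the
  best prediction of a planet's next payout is its last observed payout. M1
  therefore sets the model-free value of the chosen spaceship and the value
  of the reached planet to the just-observed reward, and shrinks the three
  unchosen/unencountered model-free entries toward zero by `1 - gamma`
  (devaluation/forgetting). Model-based planet values do not decay; the task
  gives no reason to forget a deterministic map, and only the printed
  model-free shrinkage equations have an analogue here. A configuration
  point worth noting: we considered decaying the unvisited planet's value as
  an alternative and rejected it as the default because the symmetric-start
  softmax already absorbs early-trial uncertainty; the update functions are
  small and pure, so the variant is easy to construct if needed.
* **M1 with stickiness.** Adds `rho * resp(a) + pi * stim(a)` to the mixed
  value, where `resp` indicates the action slot chosen on the immediately
  preceding trial (regardless of first-stage state) and `stim` the
  previously chosen spaceship. Both indicators are zero on the first trial
  of a session.
* **M2 / M3 (dual-system temporal-difference learners).** The model-free
  values are learned by TD steps in a fixed order: the stage-1 step uses
  `delta1 = Q2(planet) - QMF(s, a)` computed from the *pre-update* planet
  value (SARSA-style ordering), then the planet value moves by
  `alpha2 * (r - Q2)`, and finally the eligibility trace feeds
  `lambda * alpha1 * delta2` back to the stage-1 value. M3 ties
  `alpha1 = alpha2`. With all learning rates and the trace set to 1, the
  planet values coincide with M1's, which the test suite asserts as a limit
  check.

All value states start at zero, so the first choice of every session is
uniformly random under every model — a convenient, testable contract
(`log(0.5)` per first trial). The likelihood is evaluated sequentially in
compiled code; a plain-R engine composing the exported update functions is
kept as a readable reference and the two are asserted equal to numerical
precision, alongside an independent hand-enumerated oracle over all 32
choice sequences of a 5-trial fixture.

## Hierarchical estimation of treatment effects

Parameters live in an unconstrained *estimation space*: inverse-probit for
unit-interval parameters (`omega`, `gamma`, learning rates, `lambda`), log
for `eta`, identity for the stickiness biases. Each subject contributes a
latent vector of baselines and session differences, e.g.
`(omega0', gamma0', eta0', d_omega', d_gamma', d_eta')` for M1, drawn from a
multivariate normal whose session-difference means are shifted by treatment
dummies:

```
latent_i ~ MVN(m_i, Sigma),   m_i = (mu_base, mu_delta + X_i beta)
Sigma = diag(sigma) R diag(sigma)
```

with hyper-priors `mu ~ N(0, 1)`, `sigma ~ HalfNormal(0, 1)`,
`R ~ LKJ(2)`, and `beta ~ N(0, 1.5)`. Session-1 native parameters transform
the baselines; session-2 natives transform baseline + difference. An
optional serum covariate adds a dummy (1 = high serum) on the session
differences, so the low-serum amisulpride effect is `beta_ami` and the
high-serum effect `beta_ami + beta_serum`. The sticky variant extends the
latent block to ten coordinates with the same prior family (one joint
correlation block; the alternative of an independent stickiness block would
only matter for the correlation estimates, which are nuisance quantities
here). Standardized effect sizes divide a drug coefficient draw by the
pooled SD `sqrt(sigma_baseline^2 + sigma_delta^2)`, draw by draw.

### The sampler

The posterior is explored by an adaptive Metropolis-within-Gibbs scheme
written for this likelihood:

* subject latents update coordinate-wise by random-walk Metropolis with
  per-coordinate step sizes adapted during warmup (target acceptance 0.44);
  a baseline coordinate re-evaluates both sessions, a difference coordinate
  only session 2;
* `(mu, beta)` given the latents is a Gaussian linear model, so it is drawn
  exactly by a conjugate Gibbs step;
* `log sigma` and the correlation matrix update coordinate-wise; the
  correlation is parameterized by unconstrained canonical partial
  correlations mapped through `tanh` to a Cholesky factor, with the LKJ
  density and the transform's Jacobian in the target. These updates cost
  little next to the likelihood sweeps, so several rounds run per iteration
  (`hyper_rounds`);
* one non-centered scale move per `sigma` coordinate rescales the hyper-SD
  together with the subjects' deviations, holding standardized residuals
  fixed. This interweaving step is what keeps near-zero variance components
  (the half-normal/half-Cauchy "funnel") mixing.

Defaults follow the estimation contract of the study design: 4 chains, 3000
iterations with 1000 warmup (8000 retained draws), and split-Rhat < 1.01 for
every group-level quantity as the convergence criterion; any quantity at or
above the threshold is reported by warning rather than silently accepted.
Because the sampler is Metropolis-based there are no divergent transitions
to monitor; acceptance rates per block are stored on the fit object instead.
Chains are seeded deterministically from one integer seed.

The same machinery, with a Bernoulli-logit likelihood, Table-style priors
(slopes `N(0, 3)`, intercept Student-t(3, 0, 10), SDs Half-Cauchy(0, 2),
LKJ(2)) and two extra move types (a recentering move trading a population
coefficient against its partner random effects, and the non-centered scale
move), fits the stay-behaviour regression.

## Stay-behaviour regression

`build_stay_table()` codes, for every trial after the first, whether the
chosen spaceship flies to the same planet as the previous choice ("stay"),
the previous trial's points, and whether the first-stage state repeated.
`fit_stay_glm()` models staying from the full
`previous points x previous state x session x drug` factorial. Following the
methods-level description of the analysis, the complete within-subject
design (intercept, the three main effects and their interactions) enters as
correlated random effects by default; a narrower structure (random
intercept, previous-state and session slopes only, as in the figure-caption
description) is available via `random_effects = "narrow"` because the two
descriptions in the source ecosystem differ and which produced the printed
numbers is not decidable from the text. Previous points enter linearly on
their integer scale, uncentred, so a slope exponentiates directly to a
per-point odds multiplier (`odds_ratio()`). Drug terms are population-level
only; the serum variant splits the amisulpride dummy at the dichotomization
into low/high effective-dose groups and drops unlabelled amisulpride
subjects with a message. `link_slopes_to_params()` standardizes each
subject's posterior-mean session-2 point slopes and regresses them on the
computational parameters with ordinary linear models, reporting standardized
coefficients with confidence intervals and refusing (with a degeneracy
report) when a predictor has no variance.

## Model comparison and validation

`pointwise_loglik()` decomposes every posterior draw into per-trial log
likelihoods; summing a draw's row reproduces the likelihood term of the
joint density, which the tests assert. `psis_loo()` implements
Pareto-smoothed importance sampling leave-one-out cross-validation: per
observation, the largest importance weights (tail size
`min(0.2 S, 3 sqrt(S))`) are replaced by expected order statistics of a
generalized Pareto distribution fitted by the profile-posterior method with
a weak prior pulling the shape toward 0.5, then truncated at the raw
maximum; `LOOIC = -2 elpd` by construction and observations with shape
`k > 0.7` are flagged. The implementation is validated against the analytic
leave-one-out predictive density of a conjugate Gaussian model.
`pseudo_bma_weights()` stabilizes the softmax of total elpd by the Bayesian
bootstrap over observations (Dirichlet(1) weights, 1000 replicates, seeded).

`posterior_predictive_accuracy()` predicts each trial's choice per draw as
the modal choice (argmax of the choice probability; exact probability ties,
including a zero inverse temperature, credit 0.5) and averages within
subject over the default 8000 draws. The sampled-choice alternative is the
natural other reading of "predicted the choice"; the modal rule is the
default because it is deterministic given the draw, and the probability
information the sampled rule would add is already carried by the pointwise
likelihoods.

`parameter_recovery()` closes the loop — simulate from known latents, refit,
and report per-coordinate Pearson correlations, bias, and 95%-interval
coverage plus recovery of the drug coefficients. `posterior_predictive_check()`
simulates every subject at posterior-mean parameters on fresh reward walks
(per-planet reward histories of unchosen options are not observable, so the
original walks cannot be reconstructed from data) and re-runs the
stay-behaviour analysis side by side.

## The synthetic cohort generator

`cohort_spec()` + `generate_cohort()` produce complete study datasets with
known ground truth: correlated subject latents per arm, drug effects
injected on the session-difference means, two sessions of simulated play per
subject, and a trial table in the standard CSV schema. The defaults are the
package's synthetic study conditions:

* hyper-means `(0.15, -0.5, -0.5)` for `(omega0', gamma0', eta0')` and zero
  session-difference means — a cohort that mixes both controllers
  (`omega ~ 0.56` at the mean), devalues unchosen options slowly
  (`gamma ~ 0.3`), and chooses with moderate determinism (`eta ~ 0.6` in
  native units on a point scale of -4..5);
* hyper-SDs 0.8 (baselines) and 0.5 (differences), the scale at which
  subject heterogeneity is clearly visible but transforms stay well away
  from saturation;
* a mild exchangeable latent correlation of 0.15;
* `default_paperlike_spec()` echoes the published layout — arms of 38
  (amisulpride), 39 (naltrexone) and 35 (placebo), 200 trials, serum split
  18 high / 14 low among 32 measured amisulpride subjects — and injects an
  amisulpride effect of 0.787 on `d_omega'` and -0.33 on `d_eta'`, the
  reported scale of those effects. These values are generator settings, not
  estimates.

Each subject-session gets independent reward walks. The original study
reused one shuffled trajectory across participants; independent walks are
simpler and statistically conservative for group contrasts (they add
between-subject outcome variance rather than sharing it), and this is the
one deliberate divergence from the study's data-generating layout.

What the generator deliberately does not emulate: missed trials and
dropouts, reaction times, mood/working-memory covariates, genotype strata,
and any model-misspecified behaviour (real participants are not M1 agents).
Passing recovery and comparison tests on these cohorts therefore
demonstrates that the estimation machinery is correct and well calibrated
under the assumed generative family — not that the models are true of human
data.

## Problem sizes, numerics, and limitations

The test suite and the acceptance script run scaled versions of the
validation experiments, chosen as the smallest sizes at which the checks are
scientifically meaningful rather than as exhaustive reproductions: parameter
recovery uses one 50-subject cohort with 200 trials per session;
drug-effect recovery uses 20 replicate cohorts of 12 subjects per arm with
150 trials (injected effect 0.8, the reported scale) plus 20 null cohorts;
model-comparison self-consistency uses 20 replicate 30-subject cohorts of 80
trials per session with shortened chains, where the generating model's LOO
advantage is far larger than its Monte-Carlo noise. The full study-scale
fit (112 subjects, 4 x 3000 iterations) runs in minutes rather than hours
but is reserved for interactive use.

Numerical choices: softmax evaluation subtracts the maximum before
exponentiation; the log-likelihood accumulates in double precision and
non-finite accumulation is an error, not a silent `NA`; exact value ties in
prediction are credited 0.5; the correlation Cholesky clamps the remaining
squared mass at `1e-12` to survive extreme proposals; `derive_seed()` keeps
all derived seeds below `2^31`.

Known limitations. First, coordinate-wise Metropolis mixes more slowly per
iteration than gradient-based samplers; the defaults compensate with cheap
extra update rounds and the interweaving moves, but short "fast-mode" runs
(single chains, a few hundred retained draws) should be read as point-
estimate machinery, not as fully resolved posteriors — Rhat is only
meaningful with multiple chains. Second, session-difference parameters
(especially `d_gamma'`) are weakly identified at 150-200 trials per
session; their subject-level recovery correlations are genuinely modest and
the package reports rather than hides this. Third, the stay regression
conditions on the previous trial only, as the design intends; it is a
description of behaviour, not a generative model, and its subject slopes
are linked to model parameters by ordinary linear regression on posterior
means, which understates the uncertainty of both sides.
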