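---
title: "An active-inference driver: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active-inference driver: model, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aidriver)
```

## The model

`aidriver` simulates a driver agent that selects actions by minimizing
*expected free energy* (EFE) over candidate action sequences. The agent's
world is a discrete-time POMDP: hidden states evolve under a transition
model, observations are generated by a (deterministic, partially masking)
observation map, and the agent's goals are expressed as *preference priors*
over observations rather than as rewards. For a policy $\pi = a_{1:H}$ the
score is

$$G(\pi) \;=\; \sum_{\tau=1}^{H} \Big[ -\underbrace{\mathbb{E}_{Q(o_\tau|\pi)} \log P(o_\tau)}_{\text{pragmatic value}} \;-\; \underbrace{\big(H[Q(o_\tau|\pi)] - \mathbb{E}_{Q(s_\tau|\pi)} H[P(o_\tau|s_\tau)]\big)}_{\text{epistemic value}} \Big],$$

where the epistemic term is the expected information gain, written as the
posterior-predictive entropy of observations minus the expected ambiguity.
Goal seeking and uncertainty resolution are scored in the same currency, so
behaviors such as slowing before an occlusion, moving sideways to see
earlier, or glancing back at the road all fall out of one objective.

Three computational components realize this:

* a **belief filter** (`sir_update()`): the belief $Q(s)$ is a weighted
  particle ensemble updated by sequential importance resampling;
* an **EFE engine** (`expected_free_energy()`, with a compiled batch scorer
  used by the planner): policies are rolled out open-loop over a 4 s horizon
  (20 steps of 0.2 s) by propagating planning particles through the
  transition and observation models;
* a **cross-entropy-method planner** (`cem_plan()`): iteratively samples
  batches of mixed discrete/continuous action sequences, refits the
  action-sequence distribution to the lowest-$G$ elites (continuous moments
  and discrete frequencies fitted separately), and executes the first action
  of the best policy found.

Two scenarios exercise the model: passing an occluding object that may hide
a pedestrian (`run_occlusion_simulation()`), and visual time-sharing between
lane keeping and an off-road secondary task
(`run_timesharing_simulation()`).

## Belief filtering

Particles carry all scenario state variables. Weights are multiplied by the
observation likelihood, renormalized, and systematically resampled when the
effective sample size falls below $N/2$.

Two details deserve comment.

**The effective-sample-size formula.** `effective_sample_size()` returns
$N/(1+\sum_n w_n^2)$, the form this model family reports. That expression
ranges over $[N/2,\,N^2/(N+1)]$ and attains its *minimum* $N/2$ exactly at
full weight degeneracy, so a rule "resample when it drops below $N/2$" can
never fire; a filter using it would never resample and would eventually
diverge. `sir_update()` therefore triggers resampling on the conventional
estimator $1/\sum_n w_n^2 < N/2$, which is the only reading under which
resampling occurs at all. The reported quantity is kept as stated for
comparability.

**Observation kernels.** The observation maps are deterministic, which
would give degenerate 0/1 likelihoods. Continuous dimensions therefore use
a narrow Gaussian likelihood kernel. The kernel width is per-dimension:
quantities that are seen exactly when looked at (positions, heading) use a
width equal to the epistemic resolution floor (see below), so one on-road
glance collapses the lateral-position belief essentially completely within
a single step; coarsely sensed quantities (the proprioceptive steering
state, speed, pedals; 0.02 native units by default) use a wide kernel that
deliberately does *not* resolve the steering-noise realization — otherwise
observing the steering angle during an off-road glance would reconstruct
the lateral drift and no positional uncertainty could build up. A
"total conflict" reset (uniform weights plus a warning) fires only when the
observation cannot discriminate between particles at all while every
particle sits at the discrete mismatch floor; a merely distant continuous
observation still carries relative information and must not trigger it.

## The epistemic-value estimator

The posterior-predictive entropy is estimated by a leave-one-out
kernel-density estimator over the scenario's *epistemic observation
dimensions* (occlusion: the context observation and the pedestrian-position
observation with its $-1000$ null code; time-sharing: $x$, $y$, $\theta$
with null codes when off-road). Three numerical choices shape it, all
exposed as parameters:

* **Bandwidth floor** (`3e-4` native units): the effective resolution of
  predicted observations. Belief dispersion below the floor yields exactly
  zero epistemic value (the estimator short-circuits to 0, avoiding
  estimator noise on freshly reset beliefs). The *expected ambiguity* is the
  analytic entropy of the floor-bandwidth kernel, so a degenerate belief
  scores exactly zero — the regime where precise observations carry no
  ambiguity. The floor's magnitude matters behaviorally: the value of an
  observation of a dimension with dispersion $\sigma$ scales like
  $\log(\sigma/h_0)$, and it must be able to outweigh preference
  log-probability differences of several nats (the gaze preference is $-7$)
  at dispersions the steering disturbance can actually produce within an
  episode. A floor of order centimetres would put the glance crossover at
  dispersions of tens of metres and the time-sharing behavior could not be
  expressed at all.
* **Bandwidth cap** (`1` native unit) and **kernel-tail saturation**
  (squared scaled distances capped at 60): outcomes further apart than the
  cap count as distinct categories rather than one broad smoothed blob, and
  an isolated outcome carries a finite (~30 nat) surprise. Together these
  make the epistemic value of "pedestrian seen at its site" vs "null code"
  finite and invariant to the arbitrary numeric magnitude of the null code;
  with a plain Scott's-rule bandwidth the apparent entropy of the two
  clusters would grow with their arbitrary separation, and with an uncapped
  Gaussian tail a single pedestrian-present particle would contribute an
  astronomically large surprise.
* Scott's rule (clipped to the floor/cap window), a lower clamp at $-10$
  per dimension, and leave-one-out evaluation complete the estimator.

## The planner

The paper-level contract is plain CEM over action sequences; the
implementation adds standard sampling-MPC machinery, each piece motivated
by a failure mode observed without it:

* **Colored action noise** (AR(1), $\rho = 0.8$ along the horizon):
  sustained manoeuvres (a braking ramp, a lateral arc) are sampled far more
  often than under white noise, while per-step marginals are unchanged.
* **Warm start**: the action distribution is shifted one step between
  replanning cycles (standard deviations re-inflated to a fraction of the
  cold-start exploration). This provides temporal commitment: a manoeuvre
  whose payoff is indifferent to when it starts — moving left, glancing
  back — is otherwise re-postponed at every replanning step.
* **Mode inclusion and elite retention**: the first batch candidate is the
  distribution mode and the second is the best policy found so far, so the
  executed action is never worse than the incumbent plan and the best score
  is non-increasing across iterations.
* **Common random numbers**: within one planning step every policy (and
  every iteration) is rolled out under the same disturbance realizations,
  so score differences reflect actions rather than the noise lottery.
* **Smoothed spread updates**: elite standard deviations and discrete
  frequencies are blended with the previous iteration (weight 0.5); the
  mean always tracks the elites. Replacing the spread outright made the
  search freeze on first-iteration elite noise; smoothing the mean as well
  introduced closed-loop lag and lateral limit cycles.
* **Best-policy execution**: the executed action is the first action of
  the lowest-$G$ policy (the discrete gaze bit follows the fitted elite
  frequency's majority). Sampling the executed action from the refit
  step-1 marginals — the most literal reading of sampling "from a
  distribution of the first actions in the highest scoring policies" — is
  retained as an option, but it severs the first action from the later
  steps that compensated it inside its policy, and at desk-scale sampling
  budgets that uncompensated noise dominated lane and speed keeping.

Defaults: 64 policies per iteration (32 in the test profile), 12
iterations, elite fraction 0.15, planning subset of 32 (16) particles drawn
from the belief by weight, standard-deviation floor 0.002, discrete
probability clamp 0.02. None of these are statements about the modelled
driver; they are optimizer settings, and all are configurable.

## Preferences and parameters

| Preference | Form | Default | Notes |
|---|---|---|---|
| Speed keeping | Gaussian at the speed limit | mean 10 m/s, sd 1 m/s (occlusion), 2 m/s (time-sharing) | the time-sharing sd is a package choice: it must leave room for the speed-for-glance-time trade, and the preference sweep brackets it with 0.5 and 2.0 |
| Lane keeping | Triangular over the lane | bounds at the lane edges | floor $-50$: strongly unpreferred but not absolute, since the absolute prohibition is carried by the exit/conflict priors; duplicating $-1000$ here made the planner ultra-conservative about its own sampling noise near boundaries |
| Acceleration | Gaussian at 0 | sd 2 m/s² | permits the ~2.5 m/s² braking the occlusion scenario requires |
| Steering rate | Gaussian at 0 | sd 0.1 rad/s | prices steering activity; much larger values leave steering unpenalized relative to planner sampling noise |
| Gaze | Bernoulli over on/off-road | log P(on) = −7 (0 = no secondary task) | normalized: log P(off) = log(1−e^{log P(on)}) |
| Conflict / lane exit | Categorical, absolute | forbidden log-probability −1000 | −100 truncation applied only when exporting value curves for plotting |

Scenario geometry and dynamics: 0.2 s timestep; occlusion — 3 m lane, ego
from (0, 0) at 10 m/s, sight corner (28, −1.8) m, pedestrian site
(32, −3) m, 2 m safe distance, 10 s episodes; time-sharing — kinematic
bicycle (wheelbase 2.7 m, steering limit 0.5 rad), steering disturbance
0.001 rad/s in both the environment and the agent's rollouts, 30 s
episodes. The occlusion geometry is a calibration: with the corner 28 m
ahead, the straight-ahead line of sight is reached at $x = 22$ m, which a
belief-slowed approach reaches around $t \approx 3$ s.

In the occlusion scenario the conflict flag is *absorbing* along predicted
trajectories (a collision does not un-happen). With an instantaneous flag,
driving through the 4 m conflict window quickly costs less than stopping
short of it, and the cautious slow-down — the scenario's headline behavior
— inverts.

## What the simulations emulate, and what they do not

The generative process is exactly the agent's generative model (except in
the false-certainty variants, where the *prior* is deliberately wrong), on
an empty straight road. Passing behavioral checks therefore demonstrates
that the stated mechanisms produce the stated adaptations under matched
models — not that the model fits human data. Real driving adds, at least:
other road users, peripheral vision, perceptual and motor response
latencies, non-binary gaze, and learned rather than hand-set preferences.

Problem sizes: the test profile (filter 256 particles, planning subset 16,
32 policies × 12 CEM iterations) is used by the test suite and the
acceptance script; the default profile doubles the particle and batch
sizes. Filter-vs-exact-oracle checks use 5000 particles.

## Known limitations

* **Planner noise floor.** Sampling-based MPC at these batch sizes leaves
  residual lateral control noise (baseline SDLP a few decimetres), which
  compresses the contrast between the no-task baseline and visual
  time-sharing on lateral metrics, and keeps the steering-reversal count
  near its ceiling in both conditions.
* **Glance durations.** Near the glance crossover the per-step decision
  margin is ~1–2 nats, comparable to residual policy-score noise, so
  executed off-road glances are shorter and more frequent than the
  crossover analysis (`value_curves()`) predicts. The preference sweep
  still orders glance durations correctly because the −5 vs −10 contrast
  is much larger than the noise.
* **Anticipated-information overspeed.** Predicted observation entropy
  grows with speed (lateral dispersion accumulates faster), so the
  time-sharing agent cruises slightly above the preferred speed. Orderings
  between conditions are unaffected.
* **Lateral epistemic advantage.** With this geometry, one metre of
  leftward offset advances the line of sight by 10/3 m; at cautious
  approach speeds the reachable time advantage of the lateral move is about
  half to three quarters of a second, which is why the lateral variant
  resolves earlier by roughly that margin rather than a full second.

## Reproducing the experiment batteries

```{r}
# each returns per-run metrics and median/IQR aggregates
run_experiment("sim1a", n_seeds = 10, profile = "test")
run_experiment("sim2a", n_seeds = 10, profile = "test")
run_experiment("value_curves", profile = "test")
run_experiment("pref_sweep", n_seeds = 10, profile = "test")
```

The repository-level `scripts/acceptance.R` recomputes the two headline
belief-collapse timings from scratch and writes them as JSON; see the
README for how to run it.
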