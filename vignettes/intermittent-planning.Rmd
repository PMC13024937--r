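---
title: "Intermittent planning in continuous-state active inference: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intermittent planning in continuous-state active inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iaif)
```

## The problem

Sample-based active inference evaluates hundreds or thousands of candidate
action sequences per time step; for continuous control tasks the planning
phase dominates computation. Human motor control, by contrast, is well
described by *intermittent* control: open-loop movement segments punctuated
by event-triggered corrections. This package implements both regimes for a
1D mouse-pointing task — a classic continuously re-planning agent and
intermittent variants that keep sensing, inferring and acting every step
but re-plan only when an event trigger fires — so that their task
performance and planning effort can be compared under identical conditions.

## Generative process and generative model

The environment is deterministic in its state transitions and stochastic
only in its observation channel. The hidden state holds cursor position and
velocity, target centre and target half-extent. The cursor is a damped
second-order lag with zero stiffness (damping `d`, default 10 /s),
discretised by forward Euler at `dt = 0.02` s — stable for this system at
all velocities the task produces, and the simplest faithful discretisation
of the continuous dynamics. Trials last 100 steps (2 s). Positions are kept
on an internal scale of display-px / 1000 so that covariances,
divergences and preference densities are well conditioned; conversions are
exact multiplications and every exported quantity is in px.

The agent is assumed practised: its generative model has the same family
and the same nominal parameters as the process, with *uncertainty about the
damping parameter* (a Gaussian belief, default `N(10, 1)`). That
uncertainty is the only source of open-loop variance growth: the unscented
prediction appends the damping as a third sigma dimension, so fast
movements inflate the predicted state covariance while rest does not.

Observations are the cursor position, target centre, target half-extent
(each with independent Gaussian noise) and a binary in-target flag computed
from the true state and transmitted without additive noise: adding Gaussian
noise to a binary channel is ill-defined, so label noise enters only inside
the agent's likelihood model for that channel (flip probability 0.1). All
observations arrive with a fixed 100 ms perceptual delay (5 steps).

## Beliefs

The posterior factorises into independent blocks — (cursor position,
velocity), target centre, target half-extent, damping, observation noise —
and the three state blocks are updated independently to limit side effects
between channels. Each continuous channel is linear-Gaussian in exactly one
block, so its conjugate posterior is closed-form; the update blends prior
and posterior in natural-parameter space by a per-block learning rate.
`lr = 1` is exact conjugate Bayes (the test surface); the defaults are 0.5
for the cursor and half-extent blocks and 1.0 for the target centre,
because the target belief must jump as soon as the target is first seen.
The binary flag updates the two target blocks through a likelihood-weighted
sigma-point approximation, moment-matched back to a Gaussian — an
acknowledged approximation, chosen because it respects the block structure
and costs seven likelihood evaluations.

Numerical guards: covariances are re-symmetrised after every operation,
eigenvalue-clipped to the PSD cone when discretisation error makes them
indefinite, inverted with a `1e-9` diagonal jitter (internal scale), and
variances produced by the flag update are floored at `1e-12`.

## Planning

A plan is `N = 12` i.i.d. actions from a zero-mean Gaussian action prior
(sd 20 internal units/s^2 — enough for a sustained best-of-K sequence to
reach the farthest target within ~0.6 s, matching surge velocities around
1500–2000 px/s). Each of `K` plans (default 1000; the test batteries use
100) is rolled out through the unscented predictor and scored by
Monte-Carlo Expected Free Energy with `m = 32` hallucinated observations
per step. The preference distribution factorises into a Bernoulli
preference for observing the in-target flag (`p = 0.98`) and a Gaussian
preference for cursor-position observations near the *believed* target
centre (sd 50 px, frozen at planning time). Log preference densities are
floored at −1000: strictly an underflow guard — a floor anywhere near the
working range flattens the EFE landscape far from the target and leaves the
agent without a gradient to follow.

The information-gain term is implemented (mean KL between the
hallucination-updated posterior and the predicted belief) but excluded by
default: it is by far the most expensive term and did not change behaviour
on this task. Ties in the argmin are broken by the lowest candidate index.

The rollout/EFE inner loop is compiled (Rcpp) and uses a counter-style
splitmix64/Box–Muller generator keyed by (phase seed, plan index, step
index). Two consequences: plan evaluation is reproducible bit-for-bit, and
re-scoring the *remainder* of a plan with the planning-time seed replays
the planning-time draws exactly — which is how the matched-streams property
of the EFE trigger is tested.

## Triggers

* **Belief Divergence Trigger**: fires when the symmetrised KL divergence
  between the planning-time predicted belief for the current step and the
  current posterior strictly exceeds `eps_div`. The divergence sums the
  three state blocks; parameter and noise blocks are excluded because
  acting does not move them. Thresholds of 30–70 are meaningful at the
  package defaults: routine tracking contributes divergences of order 1–30,
  while first sight of the target contributes 10^3–10^4.
* **EFE Error Trigger**: at execution index `k < N`, re-rolls the remaining
  actions from the current belief with *fresh* Monte-Carlo draws and fires
  when the mean of the re-scored step-wise EFEs exceeds the mean of the
  stored planning-time values plus a slack `eps_efe` (default 0; also
  available as a relative slack). Fresh draws make the comparison noisy —
  roughly half of all steps fire near the equality boundary — which is the
  documented cost of a trigger that needs no calibrated threshold.
* **Combined**: divergence first; the EFE re-score is skipped whenever the
  divergence already fired.
* **Exhaustion**: a mandatory planning phase when `k = N`; also the only
  trigger that can fire before the first observation arrives.

A fired trigger causes re-planning at the start of the next step from the
then-current belief; planning is instantaneous in model time, and its cost
is accounted separately in `compute_units` (K·N rollout steps per phase
plus `N − k` per EFE re-score) — a hardware-independent proxy preferred
over wall-clock seconds, which the logs do not report.

## Perceptual delay bookkeeping

Two modes are implemented. The default, `direct`, fuses the delayed
observation as if it were current and compares the divergence against the
planning-time prediction for the current wall-clock step — the simplest
consistent bookkeeping. During fast movement it biases the belief backward
by roughly `gain × velocity × delay`; all compared agents share that bias,
so the comparison between classic and intermittent planning is unaffected.
The alternative, `lagged_fusion`, is the textbook delayed-measurement
filter: fuse at the observation's emission time, then re-predict to the
present through the actions executed since. It is unbiased and raises
absolute time-on-target by several points for frequently re-planning
agents, but the re-prediction inflation appears on *both* sides of the
divergence comparison and largely cancels, leaving the divergence trigger
nearly inert at thresholds of 30–70. Because the trigger study is the point
of the package, `direct` is the default and `lagged_fusion` the switch.

## Task layout and difficulty

Twelve targets: printed widths 100 px and 60 px, three distances
{450, 750, 1070} px mirrored around the start. These distances reproduce
the wide-target difficulty set ID = {2.46, 3.09, 3.55} bits exactly under
the Shannon formula `log2(1 + D/W)`; the narrow set is {3.09, 3.75, 4.24}.
The printed width is interpreted as the *half-extent* `s4` (the in-target
test is `|s1 − s3| <= s4`), with a config switch for the full-width
convention; the ID formula always uses the printed width.

## Seeds and reproducibility

A master seed derives independent sub-streams for environment noise, plan
sampling, and EFE re-scoring via an exact integer mixing function, keyed by
step. Environment noise depends only on (master seed, step), so agents with
different trigger settings face identical noise realisations — and because
the process dynamics are deterministic, two agents that happen to choose
identical actions produce identical trajectories. Trials are bit-for-bit
reproducible under a fixed seed.

## What the simulator does and does not emulate

It emulates: second-order cursor dynamics with damping, visual noise and
delay, Fitts-style target layouts, and the computational structure of
sample-based AIF planning. It does not emulate: 2D pointing, clicking,
biomechanical arm dynamics, muscle noise that scales with signal magnitude,
refractory periods, or learning of model parameters or noise across trials.
Passing tests therefore demonstrate properties of the *algorithms* under a
well-specified model of this task, not predictions for human data.

## Problem sizes used by the test suite

Unit tests run at K = 4–50 and horizons of 2–12 steps, where closed-form
and brute-force oracles are exact. The battery-level checks use K = 100
with 2 repetitions over all 12 targets, and 20-trial comparisons for the
movement-structure check — sizes chosen so the full suite completes in a
few minutes while the compared quantities (phase counts, time-on-target
differences, cost orderings) are already stable across master seeds.

## Known limitations

* The EFE trigger's near-boundary firing rate is tied to the Monte-Carlo
  sample count `m`; the `eps_efe` slack (absolute or relative) is the
  provided mitigation, defaulting to 0.
* Under `direct` delay bookkeeping the belief lags during the surge phase;
  under `lagged_fusion` the divergence trigger needs much smaller
  thresholds to be active. Neither mode is "the" correct choice for human
  modelling — the switch exists so the sensitivity can be studied.
* The binary-channel update is a moment-matched approximation; with very
  confident target beliefs it can underestimate the information in a
  surprising flag.
* With a well-specified generative model, belief divergence concentrates at
  genuinely surprising events (first target sight); under model mismatch it
  would fire more broadly, a regime the defaults do not explore.
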