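---
title: "Arousal-gated temporal-difference learning and the extinction of probabilistic rewards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arousal-gated temporal-difference learning and the extinction of probabilistic rewards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdarousal)
```

## The phenomenon

When a conditioned stimulus (CS) that predicted food with some probability
*p* stops being rewarded, how quickly the conditioned response extinguishes
depends on *p* in a way that changes with the amount of training.  After
moderate training, extinction is slowest at intermediate probabilities (an
inverted-U in the curve of trials-to-extinction against *p*); after
extensive training, lower probabilities extinguish more slowly at every
step of the grid — the partial reinforcement extinction effect (PREE).
Without any trial-level surprise signal, a plain value-learning account
predicts neither: more learned value simply takes longer to unlearn, so
extinction slows monotonically with *p*.

`tdarousal` simulates a temporal-difference (TD) account of these regimes
in which a slowly decaying *arousal* signal — surprise at the cessation of
reward — multiplies the learning rate during extinction.  The package also
simulates pharmacological scaling of the dopaminergic prediction-error
signal and its consequences for learned value and extinction rate.

## The model

**Representation.** Each trial has 10 time steps; the CS arrives at step 3
and the reward (magnitude 1) at step 8.  The stimulus is a complete serial
compound: one binary feature per post-CS time step, so the value function
`V(t)` is a lookup of one weight per step.  Two weight populations are
maintained: `w+ >= 0` (excitatory) and `w- <= 0` (inhibitory), with
`V(t) = (w+ + w-) . x(t)`.

**TD core.** At each step,

```
delta(t) = r(t) + gamma * V(t) - V(t-1)
e        <- gamma * lambda * e + x(t-1)
w+       <- max(w+ + alpha * A * delta * e, 0)
w-       <- min(w- + beta  * A * delta * e, 0)
```

with `alpha = 0.08`, `beta = 0.04`, trace decay `lambda = 0.9`, and the
trace reset at every trial boundary (inter-trial intervals are long; no
credit crosses trials).  Three structural points deserve emphasis because
they decide whether the model works at all:

* *Trace timing.* The trace accumulates the features of the **previous**
  step: `delta(t)` is the error of the prediction made at `t - 1`, so it
  credits features active then.  The CS-onset burst — which persists even
  in a fully trained agent because nothing predicts the CS — therefore
  drives no learning.  If the trace instead accumulated `x(t)`, the CS
  feature would be strengthened by its own burst on every extinction
  trial and the value would never extinguish.
* *Both pathways see every error.* The update is the same signed quantity
  for both populations; the clamps alone create the asymmetry.  Under
  fluctuating reinforcement the stationary value is then the expected
  reward (`V -> p`), which places the 25%-probability asymptote just above
  the extinction criterion — the regime in which drug-induced value shifts
  have their outsized low-probability effects, and a precondition for the
  PREE regime below.  Gating the negative weights by error sign instead
  (only negative `delta` updates `w-`) overvalues low probabilities
  (`V -> 2p/(1+p)` at the default rates) and slows extinction several-fold,
  pushing every probability past the 70-trial extinction phase.
* *Discount `gamma = 1`.* No source value is available for the within-trial
  discount, so it is a package choice.  The asymptotic CS-time error is
  `p * gamma^5` (five steps separate CS and reward).  The PREE order
  relation between p = 0.25 and p = 0.5,
  `ln(0.25 * gamma^5 / 0.12) / 0.25 > ln(0.5 * gamma^5 / 0.12) / 0.5`,
  holds only for `gamma` above roughly 0.996: at `gamma = 0.98` the 25%
  asymptote (0.226) is structurally too close to the criterion and PREE
  cannot appear for any arousal persistence.  `gamma = 1` keeps the
  undiscounted interpretation of the CS error as the learned reward
  probability and admits the PREE regime.  It is exposed as `gamma` in
  `model_params()`.

**Forgetting only during the break.** Acquisition and extinction apply no
weight decay.  During a break, each break trial scales `w+` by
`psi+ = 0.999999` and `w-` by `psi- = 0.9` and generates no prediction
errors.  After a 20-trial break the inhibitory weights have lost ~88% of
their magnitude while the excitatory weights are intact, so the CS error
rebounds: spontaneous recovery.  Re-acquisition is faster than initial
acquisition because `w+` survives extinction largely intact.

**Arousal.** Arousal `A` multiplies both learning rates.  It is pinned at
1 throughout acquisition (the animal is maximally engaged while rewards
flow).  When extinction begins, `A` is set to the reward expectation the
agent actually learned — the CS-time prediction error on the last
acquisition trial, which at `gamma = 1` is the learned reward probability
(`arousal_init = "learned"`; `"programmed"` substitutes the scheduled
probability).  Thereafter it relaxes once per extinction trial toward the
magnitude of the trial's outcome-time error:

```
A <- eta * A + (1 - eta) * |delta(reward_time)|
```

Large `eta` makes the initial, probability-ordered arousal persist;
`eta` is the axis of the regime sweeps (grid 0.91-0.99).  During the break
arousal is untouched, and the second extinction phase continues from the
arousal it inherited.  An alternative driver, the largest `|delta|` in the
trial, is available as `arousal_delta = "max_abs"`; with the default
timing both pick out the omission error at the scheduled reward time, so
the choice is inert unless the trial structure is changed.

**Drug transform.** A simulated dose `d` rescales every prediction error
before it is recorded, learned from, or fed to arousal:
`reduce: delta - d|delta|` (tonic dopamine raised, phasic contrast
reduced), `enhance: delta + d|delta|`.  Reduction underestimates reward
value and hastens extinction; enhancement does the opposite, and both act
most strongly at low probabilities, where the learned value sits closest
to the extinction criterion.  The transform is active in acquisition and
extinction alike by default (`drug_window = "both"`), matching an
infusion given before acquisition with extinction following immediately.
The extinction criterion is evaluated on the transformed error — the
drug defines what the learner (and the dopamine-reading experimenter)
sees.  A `reduce` dose must stay below 1 so a positive error can never
change sign.

**Extinction criterion.** Extinction is complete on the first extinction
trial with `|delta(CS)| < 0.12` (strict, 1-based count).  Runs that do
not reach the criterion within the 70-trial first extinction phase are
recorded at 70 and flagged `censored`, never silently truncated.

## Protocols and the schedule generator

Reward sequences are exact-count shuffles, not Bernoulli draws: a
trial-constant session has 20 trials with exactly `20p` rewards; a
reward-constant session has exactly 20 rewards in `ceiling(20/p)` trials.
Simulated acquisitions of `n` trials are concatenations of independently
shuffled 20-trial blocks (each with its exact per-block count; a
remainder block carries the balance, with half-up rounding so block
counts do not depend on banker's-rounding parity).  The standard protocol
is `n` acquisition trials, 70 extinction trials, a 20-trial break, and 40
more extinction trials.

The generator emulates the *structure* of behavioural sessions: fixed
per-session reward counts in pseudorandom order.  It does not emulate
pre-training (simulated agents start with `V = 0`, while a real animal
begins acquisition with a positive CS value), reaction-time dynamics,
satiety, or individual differences, and it imposes no run-length
constraint on omissions by default (an optional `max_run_omissions` cap
is provided but off).  Passing tests therefore certify the model's
behaviour under these idealized schedules, not quantitative agreement
with any particular animal.

## What the simulations show

With the defaults, the package reproduces the full regime map (all counts
are means over seeded schedule shuffles; see `sweep_extinction()`):

* **No arousal** (`use_arousal = FALSE`): trials-to-extinction increases
  with `p` at every `eta` — value alone predicts the wrong ordering.
* **Moderate training** (30 acquisition trials): an inverted-U appears
  from `eta = 0.93` upward; at `eta = 0.91` the high-probability cells do
  not extinguish within the 70-trial phase and no shape is assigned.
* **Extensive training** (100 acquisition trials): the curve becomes
  strictly decreasing — PREE — at `eta = 0.99`.
* **Drug doses** (30 acquisition trials, `eta = 0.97`): end-of-acquisition
  value is monotone in dose (up for enhance, down for reduce), extinction
  rate follows it, the effect is largest at `p = 0.25`, and the
  100%-normalized curve is flatter under reduction than under enhancement.

Two quantitative caveats are worth recording.  First, at
`eta = 0.99` and 100 acquisition trials the margin between the 25% and
50% cells is small — about 0.5 trials against per-cell SDs of 3-7.5 — so
distinguishing strict decrease from a flat top requires a few thousand
seeds per cell (at 8000 seeds the Monte-Carlo SE of a cell mean is ~0.1
trials).  `classify_curve()`'s default 0.5-trial tolerance, appropriate
for small-seed exploratory sweeps, sits exactly at that margin; the
threshold scripts therefore classify the high-precision means by the
order relations themselves (tolerance 0).  Second, under prediction-error
reduction at dose 0.1 the 25% condition extinguishes in roughly 20-25
trials here, not a handful: with the multiplicative transform the
end-of-acquisition transformed error (~0.15) still clears the 0.12
criterion by a wide relative margin.  A near-immediate extinction of the
25% condition would require the dose to push the learned value
essentially onto the criterion, which the magnitude-proportional
transform cannot do without flipping the sign of small positive errors.
This is the one documented quantitative disagreement with the phenomena
the package targets; the direction and low-probability dominance of the
drug effect are robust.

## Numerical and design notes

* Double precision throughout; the engine itself is deterministic — all
  randomness lives in the schedule builders, which take explicit integer
  seeds and restore the caller's RNG state.
* A compiled (Rcpp) engine and a pure-R reference engine
  (`run_protocol(engine = )`) implement identical update orders and are
  tested for exact agreement; sweeps use the compiled path.
* Sweep cells share one seed list (`seed + 0:(n_seeds-1)`), so cells are
  comparable and any run is exactly repeatable from its manifest.
* Curve classification needs at least 3 probability levels; a curve
  containing a cell with more than `max_censored` (default one half)
  censored runs is reported `flat_or_mixed` rather than classified from
  ceiling-dominated means.
* Problem sizes in the shipped tests: 20 seeds per cell for property
  checks, 1000 for the PREE-threshold check, 8000 in the threshold
  scripts; a single protocol run of 230 trials takes ~1 ms compiled.

## Limitations

* The arousal reset uses the final-trial CS error as "the learned
  probability"; a trailing run of omissions makes it a noisy estimate at
  low `p`, which is visible as the large per-seed spread of the 25% cells.
* The model is trial-structured: inter-trial interval duration,
  within-break timing, and reaction times are outside its scope.
* No fitting to behavioural data is attempted anywhere; comparisons to
  empirical extinction curves are qualitative.
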