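---
title: "Adaptive practice scheduling by efficiency thresholds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive practice scheduling by efficiency thresholds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oetsched)
```

## The problem

When a learner has a fixed amount of study time and a set of items to
master (the canonical case here is Japanese–English vocabulary pairs),
every scheduling decision trades off two classic findings: spacing
repetitions apart strengthens memory, and retrieval difficulty carries a
time cost.  A failed retrieval attempt triggers corrective feedback and is
several times slower than a fluent correct response, so difficult practice
buys its extra learning at a steep price per second.  `oetsched` implements
a model-based answer: track each item's recall probability with a
computational memory model, and always practice the item whose predicted
recall is closest to — but below — a target threshold (the
*optimal efficiency threshold*, OET).  The package contains everything
needed to study that policy end to end: the memory and latency models,
maximum-likelihood fitting, a clock-accurate session simulator, the
conventional comparison schedules, a synthetic-data generator, and
condition analytics.

## The correctness model

Recall of an item by a learner is modelled as a logistic function of a
practice-history activation plus two additive intercepts:

$$\Pr(\text{recall}) \;=\;
  \sigma\!\left(\beta_1\,a^{-d_s} N_s S^{c}
  \;+\; \beta_2\,a^{-d_f} N_f S^{c}
  \;+\; \theta_{\text{student}} + \theta_{\text{item}}\right)$$

where $N_s$ and $N_f$ count prior successful and failed attempts, $a$ is
the time since the item's first practice (seconds), $S$ is the mean
spacing between consecutive practice events (seconds), $\sigma$ is the
logistic function, and $\theta$ are log-odds offsets for learner ability
and item easiness.  The two additive components let successes and failures
contribute — and decay — differently ($d_s$, $d_f$ are power-law decay
rates); the spacing curvature $c$ is shared by both components.

Conventions the implementation fixes (the literature leaves them open):

* **Study exposures count toward $N_s$.**  Every item's first trial is a
  study presentation; its counts must start accumulating there, and a
  studied exposure is treated as a feedback-equivalent success.
* **$a$ and $S$ are in seconds and floored at 1 s.**  The power terms are
  undefined at zero elapsed time, and retention intervals span days, so a
  trial-count clock would conflate session and retention time.  One second
  is below any realizable trial gap, so the floor never distorts real
  histories.
* **Cross-session time counts fully in $a$** — the model sees real
  elapsed time, including multi-day retention gaps.
* With both counts zero the activation is exactly zero: a never-practiced
  item sits at its intercept baseline.

## The latency model

Correct-response time is an exponentially decreasing function of the
correctness model's log-odds prediction $m$:

$$RT = c_{rt}\, e^{-m} + f_c,$$

so well-known items are answered at the floor $f_c$ and barely-known items
take long.  The model only describes *correct* responses; failed trials
are charged a fixed response time (4.98 s, the empirical median) plus 4 s
of corrective feedback, 8.98 s in total.  In the simulator a correct
response is additionally capped at the 7 s response window and followed by
0.5 s of confirmation feedback.  This asymmetry — fluent successes cost
roughly 3–4 s, failures roughly 10 — is what makes difficulty expensive.

## Efficiency and the threshold policy

The expected utility of attempting an item whose success probability is
$p$ is

$$U = p\,\frac{g_{\text{correct}}}{k_{\text{correct}}}
    + (1-p)\,\frac{g_{\text{incorrect}}}{k_{\text{incorrect}}},$$

a gain-per-second expectation over the two outcomes
(`expected_utility()`).  The package implements this calculus as a
diagnostic; the *operational* policy is the threshold rule
(`next_item_oet()`): practice the item closest below the threshold, or,
when every item is above it, the item closest above — which doubles as the
natural mechanism for introducing new items, since unpracticed items sit
near their (low) baseline.  Where the optimum threshold lies is an
empirical question answered by simulation (`oet_sweep()`), not by a
closed-form rule: the gain metric itself ("percent gain" versus "logit
gain") is deliberately left as an option in `trial_gain()` because neither
is canonical.

## The simulator

`simulate_student()` runs one clock-accurate session: while elapsed time
is below the 1320 s (22 min) budget, the scheduler picks an item; a first
exposure is a 7 s study trial, later attempts are tests whose outcome is a
Bernoulli draw at the model's predicted probability; durations follow the
timing constants (11 s fixed tests in fixed-duration mode, latency-model
durations otherwise) plus a 1 s inter-stimulus interval.  A trial is
initiated only while elapsed time is under budget and always completes
(slight overrun allowed).  The final test evaluates every item at session
end plus the retention interval (default 3 days), scored by default as the
expected probability (lower variance than a Bernoulli draw; the draw
remains available for parity with empirical error bars).  With the default
arithmetic a fixed-duration session of 30 items times 4 repetitions takes
exactly 120 trials and 1320 s: $30 \times 7 + 90 \times 11 + 120 \times 1$.
The two ISI values sometimes quoted for such designs (0.5 s and 1 s) are
reconciled in favour of 1 s, the only value consistent with that total.

Populations are sampled with independent Gaussian student and item
intercepts and per-student sub-seeds, so any condition is bit-reproducible
from one master seed.  Threshold sweeps reuse one population across
thresholds (common random numbers) to sharpen between-condition contrasts;
independent seeding is a flag away.  The alternate-assumption knobs —
failure feedback cost set to 0 s, or failures 25% more potent than
successes ($\beta_2 = 1.25\,\beta_1$) — are condition fields, not code
changes.  The failure-gain multiplier defaults to *off* (`NA`): a literal
default of 1.0 would silently force $\beta_2 = \beta_1$ and override the
fitted or reference parameters, which is never what a caller wants.

## The reference parameterization

Fitted parameter values for this class of models are rarely published, so
the package ships a documented reference parameterization — explicitly
*not* an estimate from any human dataset:

```{r}
reference_params()
reference_intercept_dists()
```

The choices, and why:

* **Item intercepts center at $-2.5$** (baseline recall $\approx 8\%$).  A
  never-studied foreign-vocabulary pair is almost never recallable.  This
  matters structurally: with mean-zero item intercepts an ignored item
  would still score 50% at the final test, leaving no cost to policies
  that never introduce it, and the threshold sweep then degenerates into
  "higher is always better".
* **$\beta_1 = 0.25$, $c = 0.35$** put per-trial gains at roughly one
  logit once practice is spaced: mastering an item takes a handful of
  attempts, so the 22-minute budget genuinely binds — the session ends
  with some items unintroduced, which is what makes over-practicing easy
  items costly.
* **$d_s = 0.03$, $d_f = 0.45$**: successful retrievals are durable
  (power-law forgetting is nearly flat across the 3-day retention
  interval) while failure traces fade within minutes.  Forgetting is
  strictly positive, so immediate tests always beat delayed ones.
* **Latency (3.0, 1.2)**: a 50%-known item takes about 4.2 s, a mastered
  one 1.2 s, inside the 7 s window.

Under this parameterization, at 200 students per condition, the package's
own acceptance checks reproduce the qualitative phenomena the models are
built around: spaced conventional schedules beat massed ones;
self-paced (latency-model) conventional conditions beat fixed-duration
ones; the threshold sweep has a skewed inverted-U shape with its maximum
in the low-0.9s and *both* 0.40 and 0.98 strictly below the maximum; and
spacing widens as practice accumulates in high-threshold conditions (the
naturally emerging expanding schedule).

One documented qualitative property does *not* hold here and is left as a
failing check rather than papered over: the near-zero correlation between
student ability and completed trial count in adaptive conditions.  In this
model class with deterministic latencies that property requires every
student to be "pinned" at the threshold (equal success rates, hence equal
trial speeds, for everyone) — a regime in which higher thresholds are
strictly better and the inverted-U disappears.  Conversely, in the
budget-bound regime that produces the inverted-U, climbing an item from
its low baseline is necessarily slower for weaker students, so abler
students complete more trials and the correlation stays strongly positive.
The two phenomena pull the parameterization in opposite directions, and we
prioritized the efficiency-threshold optimum, which is the package's
subject.

## Fitting

`fit_correctness()` maximizes the Bernoulli likelihood of test-trial
outcomes.  The estimation is nested: for fixed $(d_s, d_f, c)$ the model
is linear in $(\beta_1, \beta_2,$ intercepts$)$ and solved by an
iteratively reweighted least squares logistic solver on a sparse design
with a small ridge ($10^{-2}$) on the intercept blocks (stabilizing sparse
student/item cells; slopes are unpenalized); the outer triple is optimized
derivative-free (Nelder–Mead on a box-transformed scale) within
$d \in [0, 1.5]$ and $c \in [-1, 1]$, magnitudes spanning what the spacing
literature reports.  Study trials enter only through the features — they
are exposures, not Bernoulli observations.  Only the *sum* of the student
and item intercept blocks is identified, so the student block is centered
at zero after fitting and the level carried by the items, making the
reported moments directly usable as sampling distributions for the
simulator.  Components with no supporting observations (e.g. no failures
anywhere) are flagged unidentifiable rather than silently pinned.
Goodness of fit is reported as McFadden's pseudo-$R^2$
($1 - \ell/\ell_0$ against the intercept-only null) and the rank-based
(Mann–Whitney, ties-half) AUC.

`fit_latency()` fits the two latency parameters to correct-trial response
times by constrained nonlinear least squares (Gaussian maximum likelihood;
a log-normal noise option is provided since the noise family is not
settled), via `minpack.lm::nlsLM`.  Degenerate designs — all log-odds
equal, or an exponential term that is numerically flat — are rejected or
reported as boundary fits instead of returning arbitrary numbers.

### Parameter recovery

Recovery studies refit data generated by `generate_dataset()` at known
parameters.  The generating truth used in the recovery checks is
$(\beta_1, \beta_2, d_s, d_f, c) = (0.5, 0.3, 0.2, 0.4, 0.3)$ — *not* the
simulation reference parameterization, whose failure component is
deliberately near-vanishing ($\beta_2 a^{-0.45}$ contributes a few
hundredths of a logit at typical lags): a signal that small is not
recoverable in relative terms by any estimator, which would make the check
meaningless.  The recovery truth keeps every component at a detectable
scale on the design's time scales.  At 200 participants the median
absolute relative error over ten seeded replications is within 20% for the
weights and within 0.1 absolute for the decays and curvature; those
margins are the package's acceptance gate for the estimator.

## The synthetic-data generator

`generate_dataset()` emulates a two-session parameterization study: 48
items per participant assigned equally to repetitions $\{2,4,8\}$ crossed
with target spacings $\{1,4,8,13\}$ intervening trials; retention interval
(2 min, 1 day, 3 days) manipulated between participants, split as evenly
as possible (an uneven historical split like 43/45/44 can be reproduced
via `retention_counts`); session 2 tests every item three times in
randomized blocks.  Item intercepts are drawn once for the pool (items are
shared across participants — fitting them requires that), student
intercepts per participant.  Correct-trial RTs get truncated Gaussian
noise (sd 0.3 s, floor 0.2 s).

Mixed repetitions-by-spacing sequences cannot tile a session exactly, so
session-1 orders are laid out by an earliest-due-date pass over planned
positions: each placed repetition re-anchors the item's next due slot, the
most schedule-critical (narrow-gap) item is served first among the late,
and a served-late repetition shortens the item's next target gap so
per-item mean spacing telescopes back to its target.  Realized per-cell
mean spacings stay within the ±1-trial jitter tolerance of the design
targets.  The same machinery lays out the expanding/contracting
conventional schedules, whose gap profiles are arithmetic progressions
(from one third to five thirds of the mean gap) preserving the uniform
schedule's mean interval.

What the generator does **not** emulate: the typing-timeout reset of live
experiments (a few percent of human trials), typing behaviour and partial
answers, item-selection by psycholinguistic norms, and any interference
between related items.  Passing recovery tests therefore show that the
estimator inverts *this* generative process; real logs add measurement
quirks the generator does not contain.

## Numerical choices and degenerate inputs

* Probabilities are clamped to $(10^{-12}, 1-10^{-12})$ before any
  log-odds transform; logistic inputs are capped at $\pm 745$; the latency
  exponent at 700.  No overflow for log-odds magnitudes into the hundreds.
* Exact ties in the threshold policy are broken uniformly at random from
  the running RNG stream, so they are reproducible under the session seed.
* Empty histories yield features $(0, 0, 1, 1)$; clock violations (a
  prediction requested before the last recorded event) are errors, never
  silent extrapolations.
* Every stochastic entry point takes an explicit integer seed, derives
  per-student sub-seeds from it, and restores the caller's RNG state.

## Problem sizes

The default test suite runs small fixtures (tens of students, a few
participants) in seconds; the acceptance checks run the full study
conditions — 200 simulated students per condition across the 22-threshold
grid with common random numbers, and ten 200-participant recovery
replications — in a few minutes each on a single core.

## Known limitations

* The trial-count/ability decoupling discussed above.
* The simulator models one practice session plus a delayed test; designs
  with several practice sessions can be composed from histories but have
  no first-class condition type.
* No interference or relearning-acceleration terms: items are
  independent, which is the simplifying assumption that makes word-pair
  learning the right first target.
* Conventional expanding/contracting layouts are approximate under
  congestion (exact arithmetic-progression tilings do not exist in
  general); uniform and blocked layouts are exact.
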