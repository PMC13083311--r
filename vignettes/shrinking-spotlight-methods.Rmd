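---
title: "Modeling flanker-task attention with a shrinking spotlight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling flanker-task attention with a shrinking spotlight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`sspflanker` implements a shrinking-spotlight (SSP) account of performance
in the five-arrow Eriksen flanker task. Attention is a Gaussian window over
the stimulus array; items have unit width, with the target centred at 0 and
flankers at ±1 and ±2. The window's standard deviation starts at
`sd_a0` and narrows linearly at `r_d` width-units per millisecond,

sd_a(t) = max(sd_a0 − r_d · t, 0.001),

never dropping below the minimum attentional window 0.001. Each item's
activation is the window's probability mass over its slot
(e.g. the target's is Φ(0.5/sd_a) − Φ(−0.5/sd_a)); the five activations sum
to 1 at every width. The drift of a single-accumulator diffusion process is
the activation-weighted sum times the perceptual input P, with flanker terms
signed positive on congruent and negative on incongruent trials. Congruent
drift therefore equals P at every instant, while incongruent drift starts
negative when the window is wide and rises toward P as the spotlight
converges on the target — the mechanism behind fast errors on incongruent
trials and their decline with a narrower initial spotlight.

Evidence accumulates as X_t = X_{t−1} + N(v_t · dt, σ²·dt) from X_0 = 0
between symmetric absorbing boundaries at +b (correct) and −b (error).
σ is fixed at 7.0 per 1-ms step: drift, boundary and noise are not jointly
identifiable, so σ is a unit convention and only v and b are estimated.
Response time adds a nondecision component drawn from a normal with mean
`ndt_mean` and SD `ndt_sd`, truncated at zero. The family of the
nondecision distribution is a modeling choice; it is isolated in one place
in the simulator, and a uniform variant would be a one-line swap. Decisions
not reached by `max_decision_time` (default 950 ms, the task's response
window) are censored and excluded from summaries; their proportion is
reported by the study generator.

Two time-discretisation details matter numerically. First, step k uses the
spotlight width at the step's start, t = (k−1)·dt. Second, a discrete walk
overshoots the boundary it crosses: at dt = 1 ms with σ = 7 the mean
overshoot is ≈ 0.583·σ ≈ 4 evidence units, so simulated accuracies sit
slightly above the continuous-time closed form
1/(1+exp(−2vb/σ²)) for constant drift. The test suite checks the dt = 1
walk against the overshoot-corrected boundary b + 0.583σ (Siegmund's
corrected diffusion approximation) and checks convergence to the uncorrected
closed form at dt = 0.01 ms. Model fitting always uses dt = 1, matching the
σ = 7 convention; both the data simulator and the objective's internal
simulator share the same discretisation, so fitting is internally
consistent.

## Fitting targets and objective

The model is fit to binned response-time distributions, not trial
likelihoods. Per trial type (congruent, incongruent):

* **CDF cells** — correct-trial RT quantiles at probabilities
  (0.1, 0.3, 0.5, 0.7, 0.9, 1) define six bins; the final probability
  closes the top bin at the maximum RT.
* **CAF cells** — RT quartiles of *all* responded trials at
  (0.25, 0.5, 0.75, 1) define four bins; accuracy within each bin is the
  conditional accuracy function, and carries the error information.

Candidate parameters are scored by simulating trials (12,500 per
congruency at full study scale), classifying them into the observed bins, and
summing −2 log binomial probabilities of the observed cell counts under the
simulated proportions. Simulated bin probabilities are floored at
1/(10·n_sim) so an empty predicted bin yields a large finite penalty rather
than an infinite one. Goodness of fit is a chi-square over a ten-cell
partition per trial type (six correct-CDF cells plus four error-CAF cells),
with df = cells − 1 per trial type − 6 free parameters = 12 by default (the
df convention is configurable, since reasonable conventions differ), an
acceptability flag at the 0.05 level, and RMSEA computed as
√(max(χ²−df,0)/(df·(n−1))), pooled across observations by summing χ² and df
before applying the formula.

## Optimisation

Each fit draws starting vectors from truncated normal distributions (means
[1.8, 0.017, 0.6, 60, 250, 30], SDs [1.2, 0.05, 0.3, 30, 60, 20], bounds
[0.8, 0.005, 0.2, 20, 175, 10] to [4.0, 0.15, 2.0, 150, 375, 50] at the
population stage; zero-mean with the same SDs at deviation stages) and runs
Nelder-Mead from each. Three numerical choices:

* **Common random numbers.** One simulation seed is fixed per fit and
  reused for every objective evaluation, making the surface deterministic;
  without this the simplex stalls on simulation noise. Refitting with the
  same seeds is bit-reproducible.
* **Search coordinates.** The deviance surface has a curved valley along
  near-constant sd_a0/r_d — the two parameters trade off (the convergence
  ratio sd_a0/r_d is the trade-invariant quantity). In raw coordinates a
  simplex reliably stalls part-way down this valley; the optimizer
  therefore searches in (sd_a0, sd_a0/r_d, P, b, Ndt, Ndtσ) coordinates,
  where the valley is axis-aligned, and maps candidates back to raw
  parameters for simulation. Bounds, penalties, start draws and all
  reported estimates remain in raw parameter space.
* **Bounds by penalty.** Nelder-Mead is unconstrained; candidates outside
  [0, upper] (upper = [6.0, 0.2, 5.0, 200, 450, 90] for composed values at
  every stage) are simulated at the clamped point plus a quadratic penalty
  scaled by the per-parameter start SDs.

Convergence uses optim's relative objective tolerance (10⁻⁵ at study
scale) with a per-parameter `parscale` equal to the start SDs, up to
`maxit` iterations per simplex run, one restart from the solution (a fresh
simplex escapes degenerate shrinkage on the quantised surface), and a final
polish run from the winning start.

## Hierarchical estimation

Four stages, each a multistart fit as above:

1. **Population** — one vector fit to all trials pooled.
2. **Condition deltas** — per condition, a deviation around the population
   fit to that condition's trials pooled across participants.
3. **Participant deltas** — per participant, independent of condition, a
   deviation around the population fit to that participant's trials.
4. **Observation noise** — per participant-by-condition cell, a deviation
   around population + Δcondition + Δparticipant; the bounded composed sum
   is the observation-level estimate and feeds per-observation fit
   statistics.

Condition and participant deltas are estimated independently (stages 2 and
3 both deviate from the population alone, not jointly refit). The
*within-transformed* values population + Δcondition + Δparticipant are
deliberately not truncated to the parameter bounds: they are intended for
linear models that assume untruncated values. Condition pooling in stage 2
pools trials across participants into one summary (the alternative —
summing per-participant objectives — is statistically similar but triples
the summary bookkeeping; pooling was chosen and the choice is visible in
`fit_condition_deltas`).

## Condition analyses

`condition_anova()` tests induction effects at either level:
within-transformed values with a fixed-effect GLM (residual df N − 3,
matching the hierarchical analysis convention), or observation-level values
with a one-way repeated-measures ANOVA (participant error stratum). Note
the two levels differ in what they are invariant to: the repeated-measures
layout removes per-participant shifts exactly, while the GLM on
within-transformed values relies on the hierarchical estimation itself
having absorbed participant variance into Δparticipant. Pairwise follow-ups
use estimated marginal means (emmeans) with unadjusted p-values and Cohen's
d from the model residual SD. With three conditions no sphericity
correction is applied by default. The convergence ratio sd_a0/r_d is
computed per observation and then averaged — never as a ratio of averages.

## The synthetic-study generator

`generate_study()` emulates the study design: 29 participants × 3
within-subject conditions (focused attention FA, open monitoring OM, active
control C) × 512 trials, half congruent. Condition profiles are the
reported condition means: sd_a0 = (0.42, 4.63, 4.43), r_d = (0.001, 0.105,
0.081), Ndt = (271.2, 285.0, 273.0), Ndtσ = (17.65, 31.42, 18.64) for
(FA, OM, C), with P = 0.6 and b = 60 common to all conditions (no condition
differences arise on those two). Between-participant variability is a
zero-mean truncated-normal baseline offset per parameter, shared across a
participant's conditions, with SDs set to half the start-distribution SDs
([0.6, 0.025, 0.15, 15, 30, 10]) — the study reports no between-participant
variance components, so this is a package choice, documented as a free
knob. Composed participant × condition values are clipped to small positive
floors and the stage upper bounds (FA's r_d = 0.001 sits near zero, so
roughly half of FA draws clip at the floor; the truth table records
clipping). Parameters are drawn independently across participants; the
empirical sd_a0–r_d correlation seen in fitted data is an emergent property
of estimation, not imposed by the generator.

What passing recovery tests on this generator shows — and what it does
not: the generator produces data from the model itself, so recovery
failures isolate estimation problems, but success says nothing about model
misspecification, sequential effects, fatigue, or RT contaminants present
in real data.

## Problem sizes used in validation

Validation workloads are scaled to desk hardware and chosen once:

* Parameter recovery: 20 replicate datasets of 12,500 + 12,500 trials at
  the start-distribution means, each refit with 10 starts at 12,500
  simulated trials per congruency per evaluation. Each start runs three
  short simplex rounds (maxit 75 each) rather than one long one — repeated
  re-expansion traverses the sd_a0/r_d valley markedly better at equal
  cost. Median relative recovery error of sd_a0, r_d and Ndt is the
  tracked quantity.
* Pipeline sign recovery: 10 synthetic studies of 8 participants × 128
  trials per condition, run through stages 1–3 with a desk-scale budget
  (population 5 starts, condition 10 starts at 2,000 simulated trials per
  congruency, participants 2 starts), checking that condition orderings of
  the composed estimates match the generating profiles.
* The `"study"` profile (100 starts, 12,500 + 12,500 simulated trials,
  maxit 500) reproduces the study-scale procedure and is guarded behind an
  explicit `allow_long` flag in `run_pipeline()`.

A known limitation surfaced by the sign-recovery workload: at 8 × 128-trial
scale the OM-highest ordering of *nondecision variability* is below the
estimation noise floor — even a many-minute condition-stage fit recovers
the sd_a0 pattern cleanly while scrambling Ndtσ orderings whose generating
gaps (~9 ms after pooling participant spread) are smaller than the
estimator's dispersion. Detecting that effect reliably needs the full
29 × 512 design or the real data. The attentional-narrowing (sd_a0)
component, the study's headline effect, recovers robustly at desk scale.

## Other limitations

* The binned objective discards within-bin shape; parameters whose
  signature lives in distribution tails (notably Ndtσ) are estimated with
  wide error bands at small trial counts.
* sd_a0 and r_d are weakly identified individually at moderate data sizes
  (their fitted values co-vary strongly); the convergence ratio sd_a0/r_d
  is the stable quantity, which is why it is both an analysis index and the
  optimizer's internal coordinate.
* No exact first-passage solver is provided or intended; all predictions
  are simulation-based, and estimates inherit Monte-Carlo noise from the
  fixed per-fit simulation seed.
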