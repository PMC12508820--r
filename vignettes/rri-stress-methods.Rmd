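---
title: "Methods: RRI stress detection and reactivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RRI stress detection and reactivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rristress)
```

## The problem

Acute cognitive stress shortens the RR interval (RRI, the time between
successive heartbeats) through sympathetic activation and vagal
withdrawal. In psychiatric cohorts — here major depressive disorder (MDD)
and panic disorder (PD) against healthy controls (HC) — this autonomic
reactivity is attenuated, and its within-task time course differs: after
the initial drop in the first stress minute (S1), the RRI partially
rebounds in the second minute (S2) in HC and PD but not in MDD.

`rristress` implements the full analysis chain for this setting: a
synthetic longitudinal cohort generator (clinical beat-level data of this
kind are typically unavailable for privacy reasons), preprocessing of
irregular beat series into fixed-length inputs, a one-dimensional
residual-network classifier of baseline versus stress, participant-level
repeated cross-validation comparing group-specific with pooled training,
and population-average generalized estimating equations (GEE) for the
reactivity statistics.

## The cohort generator

Each participant belongs to one of three groups (41 MDD, 47 PD, 59 HC by
default) and attends up to five visits; the default attendance
distribution (110/16/4/7/10 participants completing 5/4/3/2/1 visits,
rescaled by largest-remainder rounding when the cohort size differs)
yields 650 attended visits, hence 650 recordings per phase and 1300
analysis samples. Each visit holds a 5-minute resting baseline and a
5-minute mental-arithmetic stress phase.

Beats are generated iteratively. The interval at time $t$ is

$$\mathrm{rri}(t) = \mu(t) + A_{LF}\sin(2\pi f_{LF} t)
  + A_{HF}\sin(2\pi f_{HF} t) + \varepsilon,
  \qquad \varepsilon \sim N(0, \sigma^2),$$

and the next beat falls one interval later
($t_{n+1} = t_n + \mathrm{rri}(t_n)/1000$), stopping at 300 s, with a
300 ms physiological floor. The mean $\mu(t)$ is the participant's
baseline level ($N(\mu_0, \sigma_s^2)$ across subjects) during baseline;
during stress it is shifted by the group's reactivity
$\delta_g$ (plus a per-session $N(0, \sigma_\delta^2)$ perturbation) from
onset and raised by the group's rebound $r_g$ from the second minute
onward. The HF ("respiratory") amplitude is reduced under stress,
encoding vagal withdrawal.

Defaults (all tunable, none of them measured values): $\mu_0 = 850$ ms,
$\sigma_s = 70$ ms, $\delta = (-35, -30, -60)$ ms and
$r = (0, 12, 15)$ ms for (MDD, PD, HC), $\sigma_\delta = 8$ ms,
$A_{LF} = 25$ ms at 0.1 Hz, $A_{HF} = 40$ ms (baseline) / 20 ms (stress)
at 0.25 Hz, per-beat noise $\sigma = 10$ ms. These are plausible
resting-adult HRV magnitudes chosen once to reproduce the qualitative
ordering of interest — reactivity strongest in HC, no rebound in MDD —
and are deliberately not presented as reproductions of any measured
cohort. Visits add no systematic shift by default (an optional per-visit
shift exists for exercising the visit covariate in the GEE).

What the generator does *not* emulate: respiratory sinus arrhythmia
coupling to an actual breathing signal, circadian and medication
effects, ectopic-beat physiology, 1/f trends, or any demographic
structure. Classifier performance on this synthetic cohort therefore
demonstrates that the pipeline can learn the encoded group and phase
structure — not that any particular accuracy transfers to clinical
recordings.

## Preprocessing

Artifact filtering flags beats outside 300–2000 ms or deviating more
than 25% from the 5-beat running median, replaces them by natural
cubic-spline interpolation over beat index, and rejects series with more
than 20% flagged beats. These thresholds are conventional tachogram
heuristics; the filter is idempotent on its own output.

Each series is then resampled onto an equidistant 4 Hz grid with a
natural cubic spline through the (beat time, RRI) pairs: 1200 points for
a 5-minute phase, 240 for a 1-minute epoch. The natural boundary
condition (vanishing second derivative) is the least-assumption choice
where the method is otherwise unspecified. The grid origin is the phase
onset with half-open windows $[a, b)$, so the epoch windows B4
$[180,240)$, B5 $[240,300)$, S1 $[0,60)$, S2 $[60,120)$ partition
cleanly without double-counting boundary samples.

One grid choice deserves emphasis. A beat generator (or a real
recording) stops mid-interval, so the last beat falls up to one interval
before the phase end while the heart keeps beating. If the grid were
truncated at the last beat, the final window of every phase — B5 and
only B5 among the four epochs — would end in one to three padded zeros.
A convolutional classifier exploits such a signature immediately, which
would corrupt the B4-versus-B5 chance-level control with an artifact of
bookkeeping rather than physiology. The grid therefore extends through
the final ongoing interval (at most one beat of linear extrapolation of
the natural spline); zero padding remains in place for genuinely
truncated recordings, applied at the tail so that segment onsets stay
aligned for the convolutional model. Inputs are fed in raw milliseconds
by default — the mean-RRI shift *is* the signal — with optional
per-segment z-scoring behind a flag.

## The classifier

The model is a one-dimensional adaptation of ResNet34: a stem
(single convolution, kernel 7, stride 2; batch normalization; GELU; max
pooling 3/2), four stages of residual blocks with the 3-4-6-3 stage plan
(16 blocks, channels 64/128/256/512, stride 2 at each stage entry),
global average pooling and a single-logit sigmoid head. Each block holds
**three** convolutions and **two** batch normalizations
(conv3–BN–GELU–conv3–BN–GELU–conv1) — deliberately not the canonical
two-convolution basic block — with an additional kernel-size-1
convolution as the shortcut in every block, and GELU replacing ReLU
throughout, batch normalization preceding each activation. Kernel sizes
and the training schedule are canonical choices where the architecture
description leaves them open.

No deep-learning framework is involved: convolutions are computed as
sums over kernel offsets of row-gathered BLAS matrix products, with
hand-derived reverse-mode gradients (verified against numerical
differentiation to ~1e-11 relative error in the test suite) and an Adam
optimizer. Training minimizes binary cross-entropy (Adam, learning rate
1e-3, batch 32, at most 100 epochs by default) with early stopping on
validation loss (patience 10) and restores the best-validation weights.
The head is zero-initialized, so an untrained network outputs
probability 0.5 for every input — a useful fixed point for tests.
Padded positions are not masked; the padding convention itself is
visible to the model.

For desk-scale simulations the package provides `resnet_spec_small()`,
the same block structure at reduced width and depth; the full 16-block
network remains the default `resnet_spec()` and is exercised by the
architecture tests. Simulation problem sizes used by the packaged
checks — a 60-participant cohort with one repetition of 10-fold
cross-validation for the chance-level control, 54-participant cohorts
with a single stratified split per seed for the effect-size sweep, and
200 replicates of a 90-participant cohort for the GEE recovery study —
are the package's own choices balancing Monte-Carlo error against
turnaround.

## Evaluation protocol

Cross-validation is 10×-repeated 10-fold at the participant level:
folds are assigned to participants (stratified by diagnostic group,
round-robin within group after shuffling), and every segment inherits
its participant's fold, so no subject can contribute to more than one of
training, validation and test in any split — a hard assertion, not a
convention. Within a repetition the splits rotate (test fold $i$,
validation fold $i{+}1 \bmod k$, the rest training), so each fold serves
every role once. The *separate* strategy trains, validates and tests
within one diagnostic group; the *combined* strategy trains on the
pooled groups and stratifies its test metrics by group. Both strategies
draw the identical fold plan, so their metrics are paired. Test
predictions are pooled within a repetition (each participant is tested
exactly once per repetition) before accuracy, AUROC (midrank
Mann–Whitney, ties at 0.5), sensitivity and specificity are computed at
the fixed threshold 0.5 (validation folds serve early stopping only,
never threshold tuning); the reported summary is the mean ± SD over the
per-repetition values. The four binary tasks are baseline-vs-stress on
5-minute segments (stress positive) and B4-vs-B5 (B4 positive),
B5-vs-S1 (S1 positive), S1-vs-S2 (S2 positive) on 1-minute epochs.

## GEE reactivity analysis

The population-average models are Gaussian with identity link.
The 5-minute model regresses the per-recording RRI summary on
phase × group + visit (references: baseline, HC; visit categorical,
included when more than one level is present); the 1-minute model
regresses the per-epoch summary on epoch × group + visit (reference
epoch S1). Participants are clusters, observations ordered by visit and
phase. The working correlation is exchangeable with the moment estimator
for $\alpha$ (within-cluster residual products over
$\sum_i n_i(n_i-1)/2 - p$, scale $\phi$ = mean squared residual with the
parameter-count correction), iterated with the coefficient update to a
relative tolerance of 1e-8; the reported covariance is the Liang–Zeger
robust sandwich. AR(1) and independence working correlations are
implemented but off by default — AR(1) is fragile when clusters hold as
few as two observations. No multiplicity correction is applied across
contrasts; tests are Wald $z$ at $\alpha = 0.05$ on raw p-values.

The response summary is the mean of the 4 Hz resampled series over the
phase or epoch window — the time-weighted summary, matching what the
classifier sees. The naive per-beat mean is *not* equivalent: short
intervals are sampled more often, biasing the beat-mean low by roughly
$-\mathrm{osc\ var}/(2\mu)$ (about 1.2 ms at the default baseline
amplitudes), and since the HF amplitude drops under stress, about
0.7 ms of that bias would leak into the phase contrast — material
relative to a ~1.5 ms robust standard error at study scale.

Within-group reactivity contrasts are the phase main effect (HC) or the
phase effect plus the group interaction (MDD, PD); between-group
differences are the interaction terms alone. Under the generator the
5-minute contrast targets $\delta_g + \tfrac{240}{300} r_g$, because the
rebound acts over minutes 2–5 of the stress phase. Packaged simulations
verify ≥90% coverage of that truth by 95% robust CIs over 200 cohorts of
90 participants — a scale chosen because the uncorrected sandwich is
known to be anticonservative below roughly 40 clusters, which would test
the estimator's small-sample bias rather than recovery.

## Numerical and degenerate-input choices

* Spline boundary: natural; extrapolation (head of the grid before the
  first beat, tail into the final ongoing interval) is linear and spans
  less than one beat.
* Ties in max pooling resolve to the earliest position; all-constant
  and all-zero inputs propagate to finite probabilities.
* Batch-norm variance is floored at zero before the $\varepsilon$ =
  1e-5 stabilizer; inference uses running statistics (momentum 0.1).
* Generated intervals are floored at 300 ms rather than rejection
  sampled, keeping beat counts predictable; parameter sets pushing more
  than 1% of raw intervals non-positive trigger a warning.
* Exchangeable $\alpha$ is clamped to its validity interval
  $(-1/(\max_i n_i - 1), 1)$; singleton-cluster tables reduce exactly to
  OLS.
* Every stochastic component threads an explicit seed; stage seeds are
  derived by deterministic integer mixing so each stage is independently
  reproducible, and identical configurations reproduce artifacts
  byte-identically.

## Known limitations

The classifier results on synthetic cohorts say nothing quantitative
about clinical accuracy; headline numbers from patient data are not
reproduction targets here. The GEE assumes a correctly specified mean
model (the sandwich protects the variance, not the mean). The effect-size
monotonicity check holds the HF amplitude equal across phases, because
the vagal-withdrawal amplitude drop is itself a strong class signal that
saturates accuracy regardless of the mean shift. Training the full
16-block network at the 10×10 protocol on a full-size cohort is a
multi-hour computation in this implementation; the packaged experiments
use the reduced configuration.

## A small worked run

```{r, eval = FALSE}
cfg <- sim_config(n_per_group = c(MDD = 20, PD = 20, HC = 20), seed = 101)
sessions <- simulate_cohort_sessions(simulate_cohort(cfg))
segments <- build_segments(sessions)

fit <- fit_gee(phase_table(sessions), "phase5min")
phase_contrasts(fit)

res <- run_repeated_cv(segments, "b4b5", strategy = "combined",
                       model_spec = resnet_spec_small(240),
                       train_cfg = train_config(epochs = 8, patience = 3),
                       k = 10, reps = 1, seed = 202)
summary(res)
```
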