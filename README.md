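# rristress

Stress detection from beat-by-beat RR intervals (RRI) with a 1D residual
network, and population-average reactivity analysis with generalized
estimating equations (GEE).

## What this package is for

Acute cognitive stress (a mental-arithmetic task) shortens the RR
interval through sympathetic activation and vagal withdrawal. In
psychiatric cohorts — major depressive disorder (MDD) and panic disorder
(PD) versus healthy controls (HC) — this reactivity is attenuated, and
its within-task time course differs: after the drop in the first stress
minute (S1) the RRI rebounds in the second minute (S2) in HC and PD but
not in MDD. Beat-level clinical recordings of this kind are rarely
shareable, so the package pairs the analysis machinery with a synthetic
longitudinal cohort generator that encodes exactly this structure,
making every stage testable end to end.

The pipeline:

1. **Synthetic cohort** — three diagnostic groups (default 41/47/59),
   up to five visits per participant with a realistic attendance
   pattern (650 attended visits, 1300 phase recordings at default
   scale); per visit a 5-min resting baseline and a 5-min
   mental-arithmetic stress phase of iteratively generated beats
   `rri(t) = mu(t) + A_LF sin(2*pi*f_LF*t) + A_HF sin(2*pi*f_HF*t) + eps`.
2. **Preprocessing** — artifact filtering (range + running-median
   rules, spline repair), natural cubic-spline resampling to
   equidistant 4 Hz (1200 points per 5-min phase, 240 per 1-min epoch),
   tail zero-padding, and extraction of the B4/B5 (late-baseline) and
   S1/S2 (early-stress) epochs.
3. **Classifier** — a 1D ResNet34 variant: 16 residual blocks
   (3-4-6-3), each with three convolutions, two batch normalizations
   and a kernel-1 shortcut convolution, GELU activations, single-logit
   sigmoid head. Implemented directly on BLAS matrix products with
   hand-derived gradients and Adam — no deep-learning framework.
4. **Evaluation** — repeated k-fold cross-validation with
   participant-level, group-stratified folds (no subject crosses
   train/validation/test), comparing group-specific (*separate*) with
   pooled (*combined*) training; accuracy, AUROC, sensitivity,
   specificity as mean ± SD over repetitions.
5. **GEE** — Gaussian-identity marginal models (phase × group + visit,
   epoch × group + visit) with exchangeable working correlation,
   Liang–Zeger robust sandwich covariance and Wald z contrasts.

## Worked example

Simulate a 45-participant cohort (three visits each), fit the 5-min GEE
and inspect the reactivity contrasts:

```r
library(rristress)

cfg <- sim_config(n_per_group = c(MDD = 15, PD = 15, HC = 15),
                  visit_attendance = c(`3` = 1), seed = 21)
sessions <- simulate_cohort_sessions(simulate_cohort(cfg))
fit <- fit_gee(phase_table(sessions), "phase5min")
phase_contrasts(fit)
#>                contrast  estimate        se          z             p
#> 1  stress-baseline (HC) -47.76212 0.9596017 -49.772857  0.000000e+00
#> 2 stress-baseline (MDD) -34.90916 1.0099801 -34.564200 8.722230e-262
#> 3  stress-baseline (PD) -18.60574 1.2744108 -14.599487  2.829656e-48
#> 4     difference MDD-HC  12.85296 1.3931602   9.225761  2.815554e-20
#> 5      difference PD-HC  29.15637 1.5952925  18.276507  1.273246e-74
```

Reading this: every group shortens its RRI under stress (negative
within-group contrasts), and the configured generative truths —
`delta + (240/300) * rebound` = −48 (HC), −35 (MDD), −20.4 (PD) ms —
are recovered within Monte-Carlo error. The positive difference
contrasts are the attenuated reactivity of the patient groups relative
to HC. The same session list feeds the classifier:

```r
segments <- build_segments(sessions)
res <- run_repeated_cv(segments, "b5s1", strategy = "combined",
                       model_spec = resnet_spec_small(240),
                       train_cfg = train_config(epochs = 8, patience = 3),
                       k = 10, reps = 1, seed = 7)
summary(res)
```

which reports per-group and pooled accuracy/AUROC for discriminating
the last baseline minute from the first stress minute. A staged driver
(`run_pipeline()`) wires simulation, preprocessing, GEE and evaluation
together and writes CSV/JSON artifacts with config-hash provenance.

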