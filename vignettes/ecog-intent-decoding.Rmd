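---
title: "Decoding movement onset and direction from intracranial signals: methods"
author: "ecogdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding movement onset and direction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ecogdecode` implements a complete decoding stack for an 8-target center-out
joystick task recorded with subdural electrode grids (ECoG) at 1200 Hz:
spectral feature extraction, asynchronous detection of movement onset,
classification of the intended movement direction from the second of brain
activity *preceding* the movement, and a simulated "brain-assisted"
targeting task that quantifies what a directional prediction is worth.
Because clinical ECoG recordings cannot be redistributed, the package ships
a synthetic session generator whose ground truth makes every stage testable;
this vignette explains the models, the tunable parameters, and the design
decisions that were genuinely open.

## Feature extraction

Raw signals are re-referenced with a common average reference (CAR) filter
(after dropping any excluded channels, e.g. occipital contacts, so that
purely visual responses do not leak into the average). For every channel
and every 100 ms step, a 300 ms window (200 ms overlap) is converted to the
frequency domain with a Burg autoregressive model of order 25, evaluated as
amplitudes (square root of the AR power spectral density) in 1 Hz bins from
0 to 200 Hz. Three band averages — mu (8–12 Hz), beta (18–26 Hz) and high
gamma (70–170 Hz), all bin edges inclusive — plus the local motor potential
(LMP; the mean of the raw window) give four features per channel per step.

Decisions that the task description left open:

* **Window alignment.** Windows are left-aligned and half-open,
  `[t, t + 300 ms)`, and a step is stamped with its window *end*. Every
  feature is therefore causal and computable online; a 1.2 s recording
  yields exactly 10 steps.
* **LMP and CAR.** The LMP is computed on the CAR-filtered signal, so all
  four features see the same spatial referencing.
* **Burg estimation.** Burg's method is used because it is stable on short
  (360-sample) windows; a constant window has no spectrum and returns an
  all-zero estimate flagged `degenerate` rather than an error.
* **Rest normalization.** Dividing spectral features by their mean over
  rest steps (value 1 = no modulation, 2 = doubling) is provided for
  visualization and diagnostics; classifiers consume the raw band features,
  which are z-scored inside each training procedure. The LMP, a signed
  average with no ratio scale, is never divided.

Feature selection is a greedy forward search: starting from the empty set,
the feature whose addition maximizes cross-validated performance of the
downstream classifier (5 trial-wise folds) is added until the target size
(default 20) is reached. The selection score is *balanced* accuracy (mean
per-class recall): with one onset step per trial against dozens of rest
steps, plain accuracy saturates at the majority rate and cannot rank
features. Folds always contain whole trials, because neighbouring windows
overlap by 200 ms and would otherwise leak across the train/test boundary.

## Movement-onset detection

The joystick trace is downsampled to 10 Hz with the same moving-average
windows as the features, and a trial's onset is the first step at which the
radial extension strictly exceeds 1/8 of the maximum. Every earlier step
(back to target presentation) is a "not onset" example; one onset step per
trial; trials that never cross are excluded.

The detector accumulates 1 s of features (10 steps) in a FIFO buffer and,
once full, predicts every 100 ms whether the *next* step is an onset. The
classifier is an RBF-kernel SVM whose per-class penalties are set to the
inverse class-size ratio, compensating the heavy imbalance; its decision
values are converted to probabilities by Platt-style sigmoid calibration on
the training folds, and a step is flagged when the probability exceeds 0.3.
Performance is summarized by the F1-score, `2TP / (2TP + FP + FN)`, which
ignores the abundant true negatives. Evaluation is per step: a flag at the
true onset step is a TP, a miss there an FN, and flags elsewhere FPs —
with FPs further than 200 ms (2 steps) from every true onset reported
separately, since near-onset flags are operationally benign.

Per-feature *confidence indices* quantify which channels and bands carry
onset information: for each feature alone, the full cross-validated
detection is repeated 20 times with random re-folding, and the 20 F1 values
are tested against zero (one-sided t-test); `-log(p)` (natural log) is the
confidence index, with 3 corresponding to p < 0.05. A zero-variance F1
sample makes the t-test degenerate and is reported as a flagged sentinel
(`+Inf` when all runs succeeded, 0 when all failed) rather than a
fabricated p-value.

## Direction classification: time-varying networks with spatial edges

Let `X_t` be the M-vector of features at step `t` of the 1 s window (T = 10
steps) preceding a trial's onset. For each direction `d`, a linear-Gaussian
network models every node as a regression on its *temporal* parents (nodes
at `t − 1`) and *spatial* parents (other nodes at `t`, constrained to a
directed acyclic graph within the slice), with unit-variance Gaussian
innovations — the features having been standardized per node and slice.
Parents are time-varying: each slice has its own parent sets and
coefficients.

Fitting proceeds in three stages per node and slice:

1. **Screening.** An l1-penalized least squares problem — mean squared
   residual plus `lambda` times the l1 norm of all candidate coefficients —
   is solved over all M temporal and M − 1 spatial candidates (glmnet's
   coordinate descent; its Gaussian objective uses half the mean squared
   error, so its penalty is `lambda / 2`). Nonzero coefficients become
   candidate edges. The test suite checks this solver against an
   independent coordinate-descent oracle to an objective gap below 1e-6.
2. **Acyclicity repair.** Per-node screening does not guarantee a DAG
   within a slice. A hill-climbing pass starts from the empty spatial graph
   and repeatedly adds the candidate edge with the largest decrease in the
   total penalized residual, skipping edges that would close a directed
   cycle, until no admissible edge improves the score (ties break toward
   the lower child, then parent, index). On instances small enough for
   exhaustive search over all restricted DAGs, the greedy result matches
   the optimum.
3. **Relaxed refit.** Coefficients on the final parent sets are refit by
   ordinary least squares, removing the shrinkage bias of the screening
   stage.

A test window is scored under each direction's network by the summed
squared residual over all slices and nodes (the negative log-likelihood up
to a constant); the direction with the smallest score wins, ties going to
the lowest index. Slice 1 has no temporal term — there is no slice 0 inside
the window.

Open choices, resolved as follows:

* **Standardization across directions.** The per-(slice, node) scaler is
  computed jointly over *all* training trials and shared by all eight
  models. Per-direction scalers would let the models classify by
  direction-specific means; sharing the scaler forces the discrimination
  into the coupling dynamics, which is the model's point.
* **Penalty selection.** `lambda` is chosen by trial-wise cross-validated
  classification accuracy over a logarithmic grid (default 1e-3 to 10);
  among values within one standard error of the best, the largest
  (sparsest) wins.
* **Feature set.** The networks can consume all features or a subset (the
  forward-selected set by default in the pipeline; a band mask such as
  "high-gamma + LMP" is a cheap, effective alternative since those are the
  bands that carry pre-movement information).

## The targeting simulation

Targets sit at 45 degree spacing on a circle of radius R. When a movement
onset is predicted, the cursor is pre-positioned at distance `alpha * R`
(0 < alpha <= 1) along the predicted direction, and the remaining movement
is simulated as a straight line at the subject's average speed (mean over
trials of R divided by the onset-to-hit duration). Geometry fixes the value
of a prediction: the repositioned cursor is closer to the target than the
center was exactly when `alpha < 2 cos(e)` for angular error `e`. Hence an
error under 60 degrees improves *every* `alpha` in (0, 1], an error over 60
degrees always hurts at `alpha = 1`, and the region of points closer to the
target than R — the lens cut from the cursor circle by the circle of radius
R around the target — covers `(2*pi/3 - sqrt(3)/2)/pi`, about 39% of the
cursor circle (61% of random repositionings land farther away).

Chance-level direction statistics are computed exactly over the discrete
outcome distribution: with 8 targets the absolute angular error takes
values {0, 45, 90, 135, 180} degrees with weights {1, 2, 2, 2, 1}/8, giving
mean 90 exactly and standard deviation `sqrt(3037.5) ~ 55.11`. (A
continuous-uniform error would give `180/sqrt(12) ~ 51.96`; both are
reported rather than forced to match any particular printed value.)

`alpha` is optimized on a grid (0 to 1 in steps of 0.05) by minimizing the
mean simulated time; the curve at `alpha = 0` equals the baseline mean time
by construction. Paired per-trial comparisons report the percentage of
improved trials (ties conservatively counted as degraded) and a one-sided
paired t-test.

## The synthetic session generator

The generator emulates the statistical structure the decoders assume, with
known ground truth:

* **Trial timeline.** Target presentation, cursor presentation 1 s later,
  movement onset after a truncated-normal latency (mean 0.7 s, sd 0.25 s,
  truncated at 0.2 s — chosen as a realistic reaction-time scale; the task
  description provides no latency statistics), a 0.4 s joystick ramp to
  full extension toward the target, and a 1 s inter-trial interval after
  the hit. The labeled onset is *defined* by the same 1/8-of-maximum
  crossing rule the decoder uses, so labels and physiology are consistent
  by construction.
* **Latent band features.** A step-grid latent process holds one value per
  feature; it is iid standard normal at rest and, in the 10 steps before
  each onset, follows the direction-specific linear-Gaussian
  transition/coupling model itself (unit-variance innovations), so the
  direction classifier's generative assumption holds exactly at the latent
  level. Coupling coefficients live on the high-gamma and LMP features of
  the motor channels (about half the grid): these are the high-SNR
  features, and concentrating the coupling there mirrors where movement
  information is found empirically. Each direction's effective one-step
  transition is rescaled to operator 2-norm 0.95 — spectral-radius
  normalization is useless for sparse sign patterns, which are often
  nilpotent — keeping the process bounded while leaving the coefficients
  detectable.
* **Raw signal.** Band features are realized as amplitude modulation of
  unit-variance band-limited noise carriers (FIR band-pass filters; IIR
  designs are numerically unstable for an 8–12 Hz passband at 1200 Hz),
  summed with a slow LMP component and pink background noise. Motor
  channels additionally multiply gamma by `1 + gamma_gain` and mu/beta by
  `1 - mu_beta_suppression` during movement and add an LMP shift.
* **Null configuration.** Setting the three movement effects and the
  coupling strength to zero provably removes all task information: the
  latent recursion with zero coefficients reproduces the rest
  distribution, so chance-level behaviour of the decoders on such sessions
  is a meaningful type-I check.

What the generator does *not* emulate — and what passing tests therefore do
not show about clinical recordings: volume conduction and spatial
correlation between neighbouring contacts, line noise and movement
artifacts, non-stationary baselines, eye-movement confounds, behavioural
variability in trajectory shape, and any realistic latency distribution.

One consequence of the windowing deserves emphasis: 300 ms windows advanced
by 100 ms average roughly three adjacent latent steps, so features
extracted from the raw signal are a *smoothed* image of the latent process.
Exact-regression properties (residuals vanishing under the true
coefficients, support recovery at growing sample size) are therefore
checked on the latent series and on windows drawn directly from a known
coupling model, where they are well posed; the raw-signal pipeline is held
to the appropriate weaker standard — classification significantly above the
12.5% chance level and clean null behaviour.

## Numerical choices and problem sizes

* glmnet is called with a 30-point geometric penalty path down to the
  target value, convergence threshold 1e-12; the small restricted refits
  inside hill climbing use a dedicated coordinate descent (tolerance 1e-7,
  at most 200 sweeps) because call overhead, not arithmetic, dominates at
  those sizes.
* Hill-climbing gains are cached per candidate edge and invalidated only
  for the child whose objective changed; an edge must improve the penalized
  objective by more than 1e-12 to be added.
* Degenerate cases: constant feature columns yield empty parent sets; a
  zero denominator in the F1-score returns 0 with a warning; joystick
  traces that never cross the onset threshold invalidate their trial.
* Test and acceptance problem sizes were chosen so the full stack runs
  comfortably on one CPU: sessions of 24–48 trials with 4–6 channels for
  unit and property tests, a 200-trial session for the classification and
  recovery checks, structure recovery at N = 50 and 200 windows. These are
  the package's own standard conditions; larger sessions only sharpen the
  same comparisons.

## Limitations

The pipeline is an offline re-analysis harness, not a real-time system: it
assumes synchronized, artifact-free inputs in the documented session
layout. The direction models are linear-Gaussian; strongly nonlinear or
non-stationary coupling would be mis-specified. The targeting simulation
moves the cursor in a straight line at constant speed and ignores the
user's reaction to a suddenly repositioned cursor, which only a closed-loop
experiment could measure.
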