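---
title: "Activity recognition under domain shift: models, pipelines and study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity recognition under domain shift: models, pipelines and study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harshift)
```

## The problem

Smartphone inertial sensors make it possible to recognise eight modes of
locomotion and transportation — being still, walking, running, cycling, and
travelling by car, bus, train or subway — from five-second windows of
multichannel signal (triaxial acceleration, gravity, linear acceleration,
angular velocity, magnetic field, an orientation quaternion and barometric
pressure, sampled at 100 Hz). The hard part is *domain shift*: a model
trained on data from a phone in the trouser pocket degrades badly on data
from a phone in the hand, and a model trained on one person degrades on
another. `harshift` implements, end to end, the pipeline components that
address this setting — and a synthetic data generator that reproduces its
essential structure so every component can be exercised and measured at desk
scale, without any external dataset.

## The synthetic recording model

`generate_session()` draws a semi-Markov activity sequence (exponential
dwell times, default mean 60 s, so the window-level self-transition
probability is about `1 - 5/60`) and synthesises the 20 channels per sample:

* **Dynamic activities** (walk, run, bike) are sums of three harmonics of a
  user-specific gait fundamental (default 1.8 Hz for user 1), with slow
  amplitude and phase drift — human gait is quasi-periodic, not metronomic.
  Class multipliers put running at a higher fundamental and double amplitude.
* **Vehicle activities** (car, bus, train, subway) are AR(1) vibration with
  class-specific amplitude and spectral tilt. Car (sd 0.33 m/s², AR
  coefficient 0.965) and bus (0.40, 0.945) deliberately sit near the
  per-window *information limit*: a 5-second window supports only a noisy
  estimate of amplitude and autocorrelation, so some windows are inherently
  ambiguous. This choice makes classifier errors scattered and identically
  distributed across sessions and domains, which is the regime in which the
  downstream HMM machinery operates on real recordings. `still` is pure
  measurement noise.
* **Transient disturbances** — damped 9 Hz oscillations at Poisson times
  (default 0.12 events/s), emulating road bumps and phone handling — corrupt
  individual windows independently of their neighbours, decorrelating errors
  within an activity segment.
* **Domain shift**: each location applies a rigid rotation and a gain to the
  movement component. The transform acts at full strength on samples with a
  dynamic-activity label and at one quarter strength on vehicle-activity
  samples, encoding the physical premise that every pocket feels much the
  same vehicle vibration while limb movement depends strongly on placement.
  Users differ in gait fundamental and amplitude. Two sessions generated
  with the same seed but different domains share the underlying activity
  sequence and body-frame signal — the same recording seen from two
  placements.
* **Pressure** is a slow 0.01 hPa/s drift plus a small sensor random walk
  with a fixed (quiet) noise floor; barometers do not share the IMU noise
  level. Gravity always has norm 9.81 m/s² and quaternions are unit-norm.

What the generator does **not** emulate: biomechanically accurate gait,
sensor saturation and dropouts, magnetic disturbances indoors, and
class-conditional correlations between channels beyond the shared rotation.
Passing tests therefore demonstrate correctness and the direction of each
method's effect under controlled shift, not absolute performance on real
recordings.

## Preprocessing and features

Windows are decimated from 100 Hz to 50 Hz through an 8th-order Butterworth
anti-alias low-pass at 22 Hz applied zero-phase with reflection padding (the
standard decimation practice; `apply_iir()` by contrast is causal
single-pass, matching streaming use — its defaults, a 2nd-order low-pass at
10 Hz and a 0.3–8 Hz band-pass, bracket the human-movement band). Eight
virtual streams are appended: the Euclidean magnitudes of the five triaxial
sensors and the intrinsic yaw-pitch-roll Euler angles of the quaternion.

Per channel, `extract_features()` computes five frequency-domain features
from a Welch PSD (2-s Hann segments, 50% overlap, 0.5 Hz bins: the three
largest spectral magnitudes, spectral entropy in nats with an all-zero
signal defined to have entropy 0, and total energy) and ten time-domain
features (min, max, sd, counts above/below the mean, mean change, mean
absolute change, autocorrelations at lags 1, 10 and 25 samples, with
zero-variance autocorrelation defined as 0). An expert accelerometer set
(mean-crossing rate, band-passed peak count, interquartile range, kurtosis,
skewness, and per-axis correlations) is applied to acceleration-derived
channels only, where those quantities have a physical reading. The default
specification yields `28 * 15 + 8 * 5 + 2 * 3 = 466` features; undefined
values (moments of constant signals) are imputed as 0 so the table is
`NA`-free. The window label is the modal per-sample label, ties to the
lower class code.

## Re-ordering shuffled windows

Evaluation sets arrive as randomly shuffled five-second windows.
`reorder_data()` exploits signal continuity: the end of a window is nearly
identical to the start of its true successor, 10 ms later. Windows are
greedily joined into segments by minimising a weighted Euclidean distance
between one segment's last sample vector and another's first. Two numerical
choices matter:

* **Weights** default to the inverse squared mean one-sample change per
  channel. A genuine boundary then costs about 1 per channel while a random
  pairing costs about `(sd/step)^2`; smooth, slowly varying channels (above
  all pressure) carry the discriminative power. Inverse-variance weighting,
  the more obvious default, performs much worse here because it rewards
  large channels rather than smooth ones.
* **Threshold** defaults to the 5th percentile of sampled random-pair
  distances; joins above it are refused, which is what terminates chains at
  genuine recording gaps.
* Closed segments remain available as *continuations of other segments*
  until no pair can be joined. This matters for recall: if a finished chain
  left the pool permanently, the chain that later reaches its head could
  never join it, capping adjacency recovery at `1 - (chains-1)/n`.

On noise-free shuffles of default sessions the procedure recovers 100% of
true adjacencies with no spurious joins; recovery degrades monotonically on
average as sensor noise grows. Only local order is recovered — the
arrangement of chains relative to each other is unknowable and not
attempted.

## Temporal smoothing with an HMM

Activities are long-lasting, so isolated disagreements between neighbouring
predictions are usually classifier errors. `smooth_predictions()` decodes
the maximum a-posteriori state path (Viterbi, log-domain, ties to the lower
class code; per-step posterior decoding is available as an alternative)
of an HMM whose hidden states are true activities and whose observations
are classifier outputs. Transitions come from labeled training sequences
(counted within sequences only), emissions from the confusion matrix of an
*analogous classifier*: the same model trained inside a four-fold
cross-validation replica with contiguous quarter folds, so that its pooled
confusion matrix estimates how the deployed classifier errs on data it has
not seen. Smoothing is applied within ordered chains only, never across
chain boundaries.

Two desk-scale calibrations, both measured during development:

* `estimate_transitions()` and `emissions_from_confusion()` default to
  Laplace smoothing (pseudocount 1), appropriate for the large-count
  setting. The pipelines default to pseudocount 0.1: with only tens of
  observed transitions, Laplace smoothing flattens a true self-transition
  probability of 0.83 to roughly 0.55 and materially degrades decoding.
* Emission and transition estimates need activity segments from several
  independent recordings; the study scenarios therefore build every pool
  from two sessions. With single-session pools a class can be absent or
  represented by one segment, and its uninformative parameter row makes
  Viterbi erase the class entirely.

## Self-training

`self_train()` implements single-pass self-training: fit on the labeled
pool, predict the unlabeled target-domain set, select pseudo-labeled
instances, refit. Five selection predicates combine the classifier's
confidence `p` (maximum class probability, strict comparisons) with
agreement between the classifier and the HMM-smoothed prediction; labels
for selected instances come from either source. Original labeled instances
are never relabeled; selecting nothing returns the base model with a
warning flag, and a class taking more than 80% of the selections flags
degenerate self-training. The pipeline default is the confident-agreement
strategy (`S2`, threshold 0.5, classifier labels), chosen by sweeping the
strategy grid on synthetic validation data — the low-confidence
disagreement strategies that can help on real recordings injected label
noise under these study conditions. The full grid remains available through
`sweep_ssl_strategies()`.

## Hierarchical classification and the two pipelines

Vehicle classes (still, car, bus, train, subway) and dynamic classes (walk,
run, bike) have different physics, so a *vehicle classifier* trained only on
vehicle-class instances (ground-truth-filtered for train/validation,
prediction-filtered at test time) re-predicts every window the general
classifier called vehicle; it can only emit vehicle classes.

`run_pipeline_2019()` is the chain-smoothing pipeline for location shift:
secondary-CV HMM for the general classifier, HMM-aware self-training,
per-chain smoothing, vehicle split, the same machinery for the vehicle
classifier, merge. Five stage-wise prediction sets are recorded.
`run_pipeline_2020()` is the HMM-free pipeline for person shift: a
walking/running gate (`fit_dynamic_detector()`) followed by location
detection selects location-matched training data; quarter-fold feature
selection adapts the general classifier's features; confidence-only
self-training; vehicle reclassification with the full feature set. Four
stages are recorded. Both return a `pipeline_result` with `tidy()`,
`glance()` and `autoplot()` methods.

Macro F1 — the unweighted mean of per-class F1 over classes present in the
truth, with 0/0 defined as 0 — is the metric throughout; it reproduces the
published location-detection scores from their confusion tables exactly.

## Feature selection

The three-step selection of `select_features()`: (i) rank features by
mutual information with the label (plug-in estimator on 20 equal-frequency
bins — deterministic and auditable); (ii) walk the ranking and drop any
feature correlated above `|r| = 0.9` with an already-kept one, so the
highest-MI member of each correlated group survives; (iii) a greedy wrapper
that keeps a feature only when it strictly improves validation accuracy.
The audit trail records every decision. `adapt_across_quarters()` repeats
the procedure over four contiguous validation quarters and intersects the
selections (union for the per-cluster variant); an empty intersection
returns an empty set with a warning and callers fall back to the full set.
The wrapper is single-pass — rejected features are not revisited.

## Person clustering and location detection

`cluster_persons()` runs k-means with k = 2 (the number of unknown test
users) and 10 restarts under a fixed seed, reports the average silhouette
width, and, when ordered chains are supplied, reassigns each chain to its
majority cluster so consecutive windows agree. Good clustering features are
found by `importance_subset()`: a random forest separating "training pool
vs validation pool" ranks features by impurity importance — the features
that separate the pools are the ones encoding who is wearing the device.
Location detection is gated on dynamic activity because placement is only
visible while the wearer moves: a binary walking/running detector (argmax
decision, no tuned operating point) selects the windows from which a
four-way location classifier votes; the aggregate decision is the
plurality, invariant to window order, and zero dynamic windows yield an
explicit undecidable result.

## Study conditions and what the checks show

The acceptance measurements run on fixed desk-scale conditions chosen once:
a four-class mix (still, walk, car, bus), mean dwell 25 s, sensor noise
0.15 m/s², pools of two sessions each (train and test 2 × 400 s,
validation 2 × 350 s), ten scenario seeds; the label-level smoothing study
uses chains of 2000 windows with self-transition 0.99 and 20% symmetric
prediction noise, 100 replicates; estimator-recovery checks use 10^5-step
sequences. Under these conditions Viterbi smoothing recovers well over
eight accuracy points on noisy sticky chains, location-matched training
beats mismatched training by double-digit macro-F1 margins, and vehicle
reclassification is a small nonnegative improvement. Self-training is the
weakest effect of the four: its gains are on the order of a macro-F1 point
or less and their sign varies from seed to seed at these test-set sizes —
consistent with how marginal the method is on real recordings as well.

## Known limitations

Single-pass wrapper selection and single-round self-training (both
configurable); no Baum–Welch (the HMM is always supervised); chains are
never ordered globally; the generator's vehicle model is stationary within
a segment apart from transient bumps; macro F1 on desk-scale test sets has
high per-seed variance, which is why directional checks aggregate over
seeds.
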