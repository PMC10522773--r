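---
title: "Quantifying single-trial ERP latency: models, simulator and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-trial ERP latency: models, simulator and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ertrial)
```

## The problem

Event-related potentials (ERPs) are conventionally quantified on the
across-trial average. Late cognitive components such as the P300 and N400,
however, vary in timing from trial to trial; averaging then smears the
component, biases its amplitude downward, and hides the latency variability
itself, which is often the quantity of scientific interest (e.g. in aging
or clinical populations). `ertrial` implements a family of estimators that
assign a latency to the component in *each* trial, realigns trials on those
estimates before averaging, and scores estimators on simulated data where
the per-trial truth is known.

## The simulator

Because per-trial ground truth cannot be observed in real EEG, the package
ships a first-class generator (`synthesize_background()`,
`build_dataset()`, `simulate_study()`):

* **Component.** A half-cycle sine (`make_half_sine()`): duration drawn
  per subject from 0.100–0.300 s, peak amplitude `A`, multiplied by a fixed
  spatial pattern normalized to unit maximum (parietal-maximal around Pz by
  default, `synthetic_topography()`; `topography_from_difference()`
  extracts the pattern from a condition difference when real grand averages
  are available).
* **Jitter.** Each simulated subject receives a uniform latency
  distribution: the mean is drawn from a smooth unimodal prior over
  0.350–0.550 s and the SD uniformly from 0.040–0.080 s; per-trial
  latencies are `Uniform[mu - sigma*sqrt(3), mu + sigma*sqrt(3)]`, the
  unique uniform with that mean and SD. Latency here always means the time
  of the component *peak*: every estimator in the package targets the
  peak, so the generator anchors its truth there too. Trials with
  latencies outside 0.300–0.600 s are excluded (dropped, not resampled).
* **Background.** Per-subject surrogate EEG: eight 1/f-shaped noise
  sources plus one 8–12 Hz oscillatory source, mixed through random
  spatially smooth scalp patterns, scaled to channel SDs of 5–15 µV —
  the amplitude range and spectral shape of ongoing EEG. A 20-channel
  10-20 montage at 500 Hz with epochs −0.100–1.000 s is the default.
* **SNR calibration.** The SNR of a dataset is defined as the power at
  the peak of the deviant average over the mean per-sample variance of the
  standard trials at the target channel. A fixed-seed reference dataset
  with a nominal 10 µV component (mid-range of typical parietal P300
  difference-wave amplitudes) pins the reference SNR; for each requested
  offset (−6, −3, 0, +3, +6 dB) `calibrate_amplitude()` bisects on `A`
  until a fixed-seed measurement lands within 0.1 dB of the target. The
  calibration measurement averages the *injected component only* (the same
  sampling plan re-run on a zero background) against the noise power of
  the real standard trials: it retains the jitter smearing of the
  averaging protocol but is free of the residual-background floor that
  would otherwise make low-SNR targets unreachable. With
  no real recordings available, the synthetic reference plays the role the
  experimental dataset would otherwise play; the five offsets are applied
  relative to it.

What the generator does **not** emulate: overlapping components,
amplitude–latency correlations, non-stationary noise, trial-to-trial
topography changes, artifacts. Passing tests on this simulator therefore
demonstrates correctness of the estimators under the stated model, not
performance on arbitrary real data — the same caveat that applies to any
simulation-trained latency regressor.

## Estimators

*Averaging-based* (`avg_latencies()`): peak latency and fractional-area
latency on the per-subject average (P300 preset: Pz, 0.250–0.650 s,
positive; N400 preset: Cz, 0.200–0.600 s, negative). For the area measure
the signal is rectified to the component polarity (values of the opposite
sign clipped to zero) before cumulative trapezoidal integration; the 50%
crossing is interpolated linearly. Rectification is the standard
convention for monophasic components; an un-rectified variant would be
sensitive to baseline offsets.

*Template matching.* The template is the deviant-minus-standard difference
of grand averages, low-pass filtered at 5 Hz (zero-phase, order-4
Butterworth, applied to the full epoch before cropping to 0.300–0.600 s to
avoid edge transients). Estimators:

* `xcorr_latencies()` — per channel, Pearson correlation between template
  and trial segment at every admissible lag; curves averaged (unweighted
  by default, optionally topography-weighted) across channels; latency =
  argmax + template peak offset, earliest-lag tie-break.
* `dtw_latencies()` — dependent multichannel dynamic time warping with
  squared-Euclidean local cost summed over channels and steps
  (1,0),(0,1),(1,1); latency = mean trial time of the samples matched to
  the template's peak sample. The cost is an *unnormalized* distance, so
  the method is amplitude-sensitive by construction — a documented
  property, not a defect.
* `beamformer_latencies()` — spatiotemporal LCMV: the template is
  vectorized into a pattern `h`; the filter `w = R^-1 h / (h' R^-1 h)`
  passes `h` with unit gain while minimizing output variance. `R` is the
  covariance of vectorized segments pooled across trials and strided lags,
  shrunk toward a scaled identity with intensity `p / (n_segments + p)` —
  a sample-size-based automatic rule chosen because the feature count
  (channels × template samples) far exceeds the trial count. When
  component-free trials are available (the standard condition), passing
  them as `noise_epochs` estimates `R` from component-free data; this
  avoids the signal-cancellation bias that arises when the component
  itself dominates the covariance, and in the degenerate zero-noise limit
  the filter falls back gracefully to the matched filter.
* `ica_latencies()` — FastICA on the concatenated trials; each component
  scored by the absolute correlation between its back-projected
  trial-averaged time course at the target channel and the template; the
  best component (single mode) or top 3 (multiple mode) span the subspace
  whose sensor-space reconstruction is matched by cross-correlation.
* `iterate_latencies()` — Woody-style refinement for any of the above:
  realign on the current estimates (anchor = subject mean), re-average,
  re-filter, re-crop, re-estimate; stop at a mean absolute change below
  1 sample or 10 iterations (neither is prescribed by the underlying
  literature; 1 sample is the resolution floor and 10 iterations is far
  beyond observed convergence), with cycle detection.

*Neural networks* (`build_eegnet()`, `build_convlstm()`, `train_nn()`).
Both are implemented natively (RcppArmadillo) with full backpropagation,
Adam, minibatches of 128, MSE loss on the latency, early stopping on
validation loss with best-weight restoration:

* The convolutional regressor: temporal convolution (8 filters, 1×64, same
  padding, no bias) → batch-norm → depthwise spatial convolution (20×1,
  depth multiplier 2, max-norm 1) → batch-norm → ELU → average-pool 1×4 →
  dropout 0.5 → separable convolution (16 filters 1×16) → batch-norm → ELU
  → average-pool 1×8 → dropout 0.5 → flatten (48) → dense 1, linear.
* The recurrent regressor: electrodes mapped to a 5×5 scalp grid
  (`map_to_grid()`; rows Fp/F/C-T/P-T/O — the canonical scalp-consistent
  layout, configurable because any fixed assignment is a convention) → two
  convolutional-LSTM layers (6 filters 2×2, tanh cell activation, dropout
  0.2, recurrent dropout 0.1), each followed by batch normalisation over
  the trailing spatial axis → per-timestep maximum over filters and cells
  → flatten (101) → dense 1, linear.

Implementation choices where the reference stacks leave freedom: gates use
the plain logistic function (rather than a piecewise-linear
approximation), and one dropout mask per layer is shared across gates and
timesteps. Because the package targets desk-scale studies (hundreds of
training trials rather than tens of thousands), the harness additionally
exposes the batch size, the initial learning rate and an optional stepped
learning-rate schedule in `train_config()`, and the batch-norm moving
statistics use momentum 0.9 so inference statistics track the few updates
per epoch; the defaults remain batch 128 / rate 0.001. None of this
changes any layer shape or parameter count;
`layer_summary()` reports the per-layer counts (batch-norm rows include
the non-trainable moving statistics, the convention of standard model
summaries).

Network inputs are downsampled to 250 Hz, cropped to 0.248–0.652 s (101
samples — centring the input on the 0.300–0.600 s search window so early
and late components are truncated symmetrically; the exact crop is a
design choice, configurable in `nn_prep()`),
and standardized per trial and channel (networks train poorly on raw volt
scales). Targets are scaled affinely to [0, 1] over the search window and
the scaling is inverted at prediction; predictions are reported raw,
clipped only to the epoch span (never to the search window).

## Evaluation design

`run_benchmark()` mirrors the study pipeline: subject-grouped k-fold
cross-validation (`grouped_kfold()`; all trials deriving from one
background donor share a fold, guaranteeing train/test independence), the
template and the networks are fit on training subjects only, and the test
set is scored per method × SNR × fold by

* single-trial MAE (`mae_single_trial()`) against the chance level
  `(b − a)/3 = 0.100 s` for independent uniforms on 0.300–0.600 s
  (`random_guess_mae()`),
* subject-level MAE of the mean latency (`mae_subject_mean()`),
* relative mean absolute error of the realigned topography at the peak
  and of the realigned waveform over the component window
  (`topography_rmae()`, `shape_rmae()`), both normalized by the
  ground-truth realignment,

with fold means ± SD from `summarize_benchmark()`. Realignment anchors
default to the per-subject mean estimate; all shifts are integer-sample
(nearest sample, ties toward −∞ — sub-sample interpolation is pointless at
sample-resolution latency estimates) and shifted-in edges are masked (per
sample denominators) rather than zero-padded, so no artificial taper is
introduced at window edges.

For experimental-style analyses the package provides the pooled
reaction-time correlation (`rt_correlation()`; the per-subject correlations
are attached as an attribute since pooling is a design choice), ordinary
least-squares age regression with RMSE (`age_regression()`), classical
one-way ANOVA with Bonferroni-corrected pairwise post hocs
(`group_effects()`, Welch variant by flag), and the N400 effect amplitude
(mean of the incorrect-minus-correct-average difference at Cz over
0.300–0.500 s, with optional realignment; `n400_effect_amplitude()`).

## Numerical conventions

* Internal unit is volts; seconds relative to stimulus onset; sample `i`
  (1-based) sits at `t0 + (i-1)/srate`; windows are closed on the left,
  open on the right.
* Downsampling uses a zero-phase order-6 Butterworth at 80% of the new
  Nyquist before subsampling, so latencies acquire no filter delay.
* All stochastic stages draw their seed deterministically from a global
  seed plus a stage label (`derive_seed()`); identical specs and seeds
  produce bit-identical datasets, and network training is deterministic on
  a fixed seed (single-threaded C++ with its own Mersenne-Twister).
* Degenerate inputs: flat windows return the earliest sample with a
  warning (peak latency); zero rectified area, zero true topography and
  zero-variance correlation inputs are errors; an all-zero segment
  covariance falls back to the identity (matched filter); rejected-epoch
  sets may legitimately be empty (warning, not error).

## Problem sizes

The shipped tests and the acceptance script run the full pipeline at
desk scale: 14 simulated subjects × 100 trials at two SNR offsets with
2-fold grouped cross-validation for the benchmark, a few hundred trials
for the noise-free recovery checks, and short fixed-epoch budgets for
network training. These sizes were chosen so the whole suite documents the
behavior of every component while remaining runnable on a laptop core;
they are deliberately smaller than a full study (more subjects,
repetitions and folds simply shrink the error bars).

## Known limitations

* The ICA subspace reconstruction inherits FastICA's sign/order
  indeterminacy; scores are absolute correlations, so sign is irrelevant,
  but component selection can differ across seeds on borderline data (the
  fit is retried once with a new seed on non-convergence).
* The DTW estimator is amplitude-sensitive and is expected to perform
  near chance on low-SNR single trials; it is included as a documented
  comparison point, not a recommendation.
* The beamformer's covariance needs either component-free trials or
  enough trials per subject; with very few trials the shrinkage rule
  pushes it toward the matched filter.
* Training the networks on simulated data transfers to real data only as
  far as the simulator's assumptions hold (component shape, fixed
  topography, noise model) — the fundamental trade-off of
  simulation-trained regressors.
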