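---
title: "Decoding finger movement from multi-channel nerve recordings: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger movement from multi-channel nerve recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An implanted peripheral-nerve interface records extracellular activity on
16 channels — eight on the median nerve, eight on the ulnar nerve — while
the subject intends hand movements. The decoding task has two coupled
parts: *classification* of which of the five fingers are active (a 5-bit
state; the task set covers nine of the 32 possible states: five
single-finger flexions, index pinch, tripod pinch, fist, rest) and
*regression* of ten joint trajectories (MCP and PIP flexion of each
finger), glove-normalized to $[0,1]$ with 0 the resting position.

Decoding is *pseudo-online*: the continuous recording is cut into 4 s
causal windows advanced in 100 ms steps, so each decision uses only past
samples, emulating real-time operation.

## Feature extraction

Raw acquisition runs at 40 kHz (7.68 Mbps over 16 channels at 12 bits).
The stream is decimated to 5 kHz and band-passed to 25–600 Hz, where most
of the decodable power lives. Each 4 s trial is then reduced to a
$224 \times 200$ matrix: 14 classic time-domain features (zero crossings,
slope sign changes, waveform length, Wilson amplitude, mean absolute,
mean square, RMS, v-order 3, log detector, difference absolute standard
deviation, maximum fractal length, myopulse percentage rate, mean
absolute value slope, weighted mean absolute) per channel
($16 \times 14 = 224$ rows), over 100 ms windows advanced by 20 ms (80 %
overlap; $4\,\mathrm{s} / 20\,\mathrm{ms} = 200$ columns). The feature
stream runs at 179.2 kbps — a more than 40-fold compression of the raw
stream — which is what makes shallow decoders practical.

Ambiguities in the classic formulas are fixed as follows and verified
against brute-force oracles in the tests:

* the "sign" in the counting features (ZC, SSC, WA, MPR) is the indicator
  $\mathbb{1}[u>0]$; ties count zero, so counts are non-negative;
* ZC counts sign changes of the *demeaned* window;
* logarithms are natural; $|x|$ is floored at $10^{-12}$ inside the log
  detector, and MFL floors its summed squared differences the same way,
  so every feature is finite on all-zero windows;
* the standard deviation uses the sample ($N-1$) denominator;
* V3 uses the signed real cube root;
* MFL $= \log \mathrm{DABS} + \tfrac12\log(N-1)$ exactly — an identity
  the tests assert to $10^{-9}$.

**200-column policy.** Only 196 complete 100 ms windows fit strictly
inside a 4 s trial. Column $t$ is computed from the 100 ms ending at
$t \times 20$ ms; the first four columns reach before the trial start and
use real preceding samples when the parent recording has them (the
pseudo-online case — they always exist past the first trial) and left
zero-padding otherwise. This reconciles the 200-column geometry with
causality.

**Normalization.** Each feature type is divided by one fixed constant
shared across channels: the 99th percentile of its absolute value over
the *training* split. Whether the fixed constants should be per-feature,
per-channel, or per-pair is genuinely open; per-feature is the most
robust choice at small sample sizes and is the one implemented. Constants
are never refitted on held-out data (a hash guard in the tests enforces
this).

## Decoding strategies

**Two-step (2S).** A multi-label classifier (five independent binary
outputs, threshold 0.5) predicts the finger state; only the two joint
regressors of each active finger run, and inactive joints are set exactly
to zero. Gating eliminates the false-positive "wiggle" of idle joints and
skips most model invocations on rest-heavy data. Regressors are trained
only on trials where their finger is active.

**One-step (1S).** All ten regressors run on every trial, trained on the
full dataset. Inactive samples outnumber active ones roughly 5:1 to 10:1
in protocol-like sessions (the simulator reproduces this band), so
training uses inverse-class-frequency sample weights — the simplest of
the usual imbalance remedies, chosen over augmentation for determinism.

A classifier state outside the 9-gesture codebook is honored as-is:
per-finger gating needs no codebook lookup, which is also what makes the
design extensible to new gestures without architecture changes (asserted
in the tests by training on a synthetic tenth gesture).

## Models

Neural architectures follow the published layer counts; exact widths are
this package's documented defaults, chosen so parameter counts land near
the published totals (about 1.5 M for classification, about 0.77 M for
the ten regression models combined; the tests audit a $[0.5\times,
2\times]$ band):

* classification CNN: conv1d (32 filters, kernel 5, stride 2 over time)
  → FC 512 → FC 128 → FC 5 — layer counts (conv, LSTM, FC) = (1, 0, 3);
* classification RNN: 64-unit LSTM in place of the convolution;
* regression (both variants): conv1d ×3 (32/32/16 filters, kernel 5,
  stride 2) → LSTM (32 or 64 units) → **single-unit LSTM** that emits the
  trajectory directly — layer counts (3, 2, 0). A per-step linear head
  would be conventional, but it would add a fully-connected layer where
  the published table reports none; the 1-unit LSTM keeps the published
  shape honestly. Outputs are emitted at the 22 time steps surviving the
  strided convolutions (their receptive-field ends) and interpolated back
  to the 200-step grid; predictions are clipped to $[0,1]$.

Training uses Adam with $\beta_1 = 0.99$ (as printed — deliberately not
the conventional 0.9), $\beta_2 = 0.999$, L2 weight decay $10^{-5}$,
minibatch 38, and exactly 10 minibatches per epoch; the learning rate
starts at 0.005 and is cut tenfold after two epochs without
training-loss improvement, stopping at $10^{-6}$ or `max_epochs`
(default 200; the demo configurations use 10–40). Small training sets
are resampled with replacement so an epoch keeps its printed size —
without this the patience-2 schedule collapses the rate prematurely on
noisy small-sample loss estimates. The regression training loss is mean
squared error, matching the evaluation metric. All gradients in the
native engine are finite-difference-checked in the test suite.

Baselines take reduced inputs: classification models use the 224-vector
of per-row means; regression models use, per 20 ms step, the 30 leading
PCA scores of the feature column (PCA fitted on training data only).
Published hyperparameters are kept exactly: RBF-kernel SVM
(classification) and cubic polynomial kernel (regression) with $C = 1$;
random forests of 5 / 10 trees with depth 3; an MLP of 300-300-300-50
units for regression and, for classification, the CNN plan with its
convolution replaced by a 200-unit dense layer. Because no SVM, forest
or neural runtime is available in the target environment, all of these
are implemented natively: a simplified SMO solver for the SVC, an exact
explicit cubic feature map (5,456 monomials on 30 inputs) with primal
subgradient descent for the SVR, and depth-capped CART trees. Kernel
methods cap their training sets (1,200 / 2,000 points, subsampled
deterministically) to bound the kernel matrix; per-step baselines train
on every fifth time step for the same reason.

**Default families.** The pipeline default is a random-forest classifier
with RNN regressors. The published comparison itself reports RF
classification within 0.01 of the CNN (≈0.99) and recommends RF for
portable deployment; at desk scale the 1.7 M-parameter CNN additionally
memorizes the time axis of the few hundred available trials (perfect
training accuracy, chance held-out accuracy), which is an honest
small-sample failure mode, not a defect of the architecture — the CNN
remains implemented, audited and tested.

## Evaluation

Per-finger classification metrics are computed one-vs-rest from the 5-bit
outputs: sensitivity, specificity, precision, *balanced* accuracy
$(\mathrm{Sens}+\mathrm{Spec})/2$ — used because inactive-finger samples
dominate — and $F_1 = 2\,\mathrm{Sens}\cdot\mathrm{Prec} /
(\mathrm{Sens}+\mathrm{Prec})$. Degenerate denominators (class absent,
no errors) resolve to 1, documented in `?classification_metrics`.

Regression uses MSE and VAF $= 1 - \sum(\hat y - y)^2 / \sum(y - \bar
y)^2 \in (-\infty, 1]$. VAF is undefined (NA) for zero-variance ground
truth. Negative VAF values are retained in raw output and excluded only
at summary level, with the count reported — never silently deleted.
Across trials, $y$ and $\hat y$ are concatenated per DOF before computing
VAF (rather than averaging per-trial VAF), which is stabler on short
trials where per-trial variance is small.

**Leakage-free splitting.** Overlapped windows share raw samples, so a
random per-trial split leaks. The regression split cuts the timeline into
contiguous blocks, draws whole blocks into validation, and drops training
trials whose sample range intersects any validation trial (the guard
gap); an audit function proves zero shared sample indices. The pipeline
sizes blocks at about two windows (8 s): long enough that guard gaps cost
few trials, short enough that both sides of the split see every gesture —
with a handful of coarse blocks, a blocked gesture protocol would place
whole gestures on one side and validation would measure extrapolation to
unseen gestures, which nothing in this design is asked to do.
Classification uses gesture-stratified 5-fold assignment. Model
comparisons use paired t-tests on per-trial scores with Bonferroni
correction, reporting exact ties explicitly.

## The synthetic world

No public recording exists for this paradigm, so the package bundles a
simulator that emulates the training protocol: gestures performed in
blocks, `n_repetitions` cycles each, every cycle 4 s alternating rest and
flexion. Choices, and what they do and do not establish:

* **Envelope:** raised-cosine ramps into and out of a plateau, centered
  in the cycle; by default half the cycle (2 s) is spent off rest,
  reading "alternating between resting and flexing" as an even split.
  This default also reproduces the published 5:1–10:1 negative:positive
  imbalance at the 20 ms step level on an equal-repetition 9-gesture
  session — it was set from the protocol description, not tuned to that
  band. MCP and PIP of one finger share the envelope scaled by 1.0 / 0.9;
  real joints are not this collinear, so per-joint differences in real
  data are understated.
* **Carrier:** Gaussian noise band-limited to 25–600 Hz (where the
  decodable power is reported to live), amplitude-modulated per channel
  by `baseline + gain[channel, finger] * envelope`. The default gain map
  gives thumb/index/middle smooth tuning profiles over the median bank
  (channels 1–8) and ring/little over the ulnar bank (9–16), with the
  thumb exactly zero on ulnar channels, mirroring the reported
  median-nerve localization of the thumb.
* **Noise:** white Gaussian per channel, scaled so the
  modulated-carrier-to-noise variance ratio equals `snr_db` (default
  20 dB). Interference, artifacts, electrode drift and cross-day
  nonstationarity are *not* modeled; a green test here establishes that
  the pipeline recovers a stated world, not clinical performance.
* **Determinism:** one seed controls the whole session; equal seed and
  config give byte-identical output, and the generator restores the
  caller's RNG state.

## Numerical choices and degenerate inputs

* Band-limiting is zero-phase FFT filtering with raised-cosine transition
  edges (exact zero outside them, so stop-band attenuation exceeds the
  40 dB contract); a real-time port must switch to causal IIR filtering,
  which this offline tool deliberately does not emulate. Decimation is
  preceded by an anti-alias low-pass at 0.4 of the target rate.
  Down-sample-then-band-pass order follows the published processing
  description.
* The finger-activity threshold on trajectories defaults to 0.1; the
  glove-to-"active" rule is unstated in the source material, and 0.1
  cleanly separates the raised-cosine ramps from rest.
* The trial trajectory is stored at the 20 ms feature step, taking the
  value at each feature-window end (label alignment is otherwise
  unstated).
* A DOF with no active training trials under 2S gets a constant-zero
  regressor with a message (the gate keeps it at zero anyway); an
  explicitly requested `active_only` fit on such data errors.
* Tripod pinch is encoded thumb+index+middle (`11100`); the index-pinch
  code is stored as the published literal `00011` even though under
  thumb-first bit order that names ring+little — the bit order is an
  explicit, configurable attribute of the codebook rather than an
  assumption.

## Known limitations

* The clinical results of the source study (its per-finger accuracy
  table and MSE/VAF figures) are out of scope: the recordings are not
  public, and nothing here claims to reproduce them.
* Architecture widths inside the published layer counts are not
  recoverable from the text; parameter totals are audited to a factor of
  two, not matched exactly.
* The SMO and primal-SVR solvers are sized for desk-scale data (their
  training-set caps are documented above), not for production SVM work.
* Everything is offline/pseudo-online; no streaming execution or latency
  measurement is provided.
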