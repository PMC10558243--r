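---
title: "Decoding bladder state from multichannel ENG: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding bladder state from multichannel ENG: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the signal model
behind the synthetic generator, the preprocessing and feature definitions,
the cross-validation protocol, and the design decisions taken where the
problem admitted more than one reasonable answer. It states no empirical
result beyond what the test suite and `scripts/acceptance.R` themselves
compute.

## The decoding problem

A multichannel intrafascicular electrode in the pudendal nerve records
electroneurogram (ENG) activity on up to 32 active sites at 24 414 Hz while
the bladder is emptied, filled by saline infusion, and allowed to leak.
Each recording interval carries one of three labels — `baseline`, `full`,
`micturition` — and the task is a three-class classification of short time
windows of the multichannel signal. Class segments are kept at equal
duration so the problem is balanced by construction, and performance is
reported as balanced accuracy (BA), the unweighted mean of per-class
recalls divided over the three classes so that BA ∈ [0, 1]. (A common
shorthand writes BA as the plain sum of the three recalls; we normalize by
the class count, which is the convention that makes reported percentages
interpretable.)

## The synthetic session generator

No public dataset of this kind exists, so the generator is a first-class,
tested component, not a fixture. It emulates:

* **State-dependent spiking.** Each functional channel fires as a renewal
  process with an absolute refractory period: inter-spike intervals are
  `refractory + Exp(rate_adj)` with `rate_adj = rate / (1 − rate·refractory)`.
  This parametrization makes the *realized* mean rate exactly the requested
  rate (mean ISI = 1/rate), reduces to a homogeneous Poisson process at
  `refractory = 0`, and keeps the empirical-rate-recovery property testable
  at any rate with `rate·refractory < 1`. A naive
  exponential-plus-dead-time process would silently fire ~25 % slow at
  80 Hz with a 4 ms refractory.
* **Extracellular waveforms.** Spikes are rendered as a biphasic
  difference-of-Gaussians template ~1.2 ms wide, small positive lobe then a
  dominant trough ~0.35 ms from onset. Its energy is concentrated in the
  1–6 kHz band, so templates survive the pipeline's band-pass — the
  standard localization of somatic-fiber spikes that motivates those
  cutoffs in the first place.
* **Dead channels.** A configurable number of sites (default 5; acute
  implants typically lose 4–7 to impedance failure) carry broadband noise
  only — not a flat line — because real nonfunctioning channels are kept in
  the analysis to stress the classifier, and a flat channel would be
  trivially ignorable.
* **Protocol timing.** Segments follow the experimental order
  baseline → full → micturition at equal durations (default 60 s each).
  Optional physiological traces at 1526 Hz mimic the infusion protocol:
  infused volume ramps monotonically at a 50 ml/min pace toward 150 ml, and
  intravesical pressure rises from ~2 mmHg toward a micturition peak.

Firing rates and amplitudes per state are free parameters: the animal
literature gives no quantitative account of pudendal afferent modulation
across bladder states, only that the states are discriminable. The defaults
(10/40/90 Hz, amplitudes 8/10/12 against unit noise) are chosen once to
produce a clearly separable study, and tests construct harder regimes by
shrinking those contrasts — including identical-state configurations that
must decode at chance.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: correlated noise across channels, electrode
drift and movement artifacts, bursting or adapting firing statistics,
overlapping spike waveforms from multiple fibers per site, and genuinely
nonstationary state transitions. A perfect BA on the default synthetic
study validates the pipeline's correctness and leakage-safety, not in-vivo
decodability.

## Preprocessing

* **Band-pass.** "4th-order Butterworth, 1–6 kHz" is implemented with the
  low-pass-prototype convention (`signal::butter(4, …)`, 8 realized poles),
  matching the scipy convention of the reference software ecosystem; the
  reading is recorded in the `filter_spec` metadata. Application is
  forward–backward (zero phase) because the pipeline is offline and window
  boundaries must not shift relative to labels; a causal single-pass flag
  exists for streaming parity. The test suite checks the realized response
  against the analytic (prewarped) Butterworth magnitude oracle: passband
  gain within 5 % at 3 kHz, ≥ 40 dB attenuation at 100 Hz.
* **Undersampling** is plain decimation by 2 with no extra anti-alias
  filter: the band-pass already confines content below the post-decimation
  Nyquist (24 414/2/2 = 6103.5 Hz > 6 kHz). A spectral test asserts < 1 %
  of energy above 6 kHz after the chain.
* **Spike detection** is quality control only — features are computed on
  the continuous filtered signal, not on spikes. The threshold rule is
  `k · MAD/0.6745` with `k = 4.5` and negative polarity by default (our
  choice; no rule is canonical), one extremum per supra-threshold run, and
  refractory enforcement where the earlier event wins. When the robust
  noise estimate is degenerate (a noise-free synthetic render is mostly
  exact zeros), the threshold falls back to half the peak deflection. Note
  that sample rounding can shrink a true ISI marginally below the
  generator's refractory; QC comparisons therefore use a detector
  refractory slightly below the generator's (e.g. 3.5 vs 4 ms).

## Features and leakage safety

The nine per-window features are MEAN, VAR, SKEW, KUR, MAV, WL, MAX, AMP,
POW. Definitions that required a decision:

* **MAV** is mean absolute value, the standard myoelectric feature behind
  the abbreviation (one figure caption in the source literature expands it
  as "maximum amplitude", but MAX already covers the maximum, and the
  accompanying discussion says "mean absolute value").
* **WL** ("wavelength") is waveform length, Σ|xᵢ₊₁ − xᵢ|, the classic EMG
  feature; **AMP** is peak-to-peak (max − min), distinct from MAX.
* **VAR/SKEW/KUR** use population (biased) moments, KUR is excess
  kurtosis; **POW** is the mean squared sample, so it is window-length
  invariant. Zero-variance windows take SKEW = KUR = 0 so dead or clipped
  channels never produce non-finite table entries.

The train/test split happens on the raw timeline, per class interval,
*before* any windowing (final 10 % of each interval is test material), so
overlapping training windows can never share samples with test windows.
Training windows use 0.55 s length with 0.11 s (20 %) overlap, test windows
no overlap. Standardization is always fitted on training data (ε = 1e−12
floor for zero-variance columns) and applied to test data with those
statistics; fitting on a test table is a contract violation that errors.
Row shuffling is seeded and label-aligned.

## Nested cross-validation

Outer folds are contiguous-in-time, class-stratified blocks rather than
random rows: the inner protocol ("shift a validation block along the time
dimension") implies temporal structure, and random row folds would let
overlapping neighbor windows leak across folds. Within each outer training
set the inner loop slides a contiguous per-class validation block through
`n_inner` positions; every grid point is scored by mean inner BA and the
best (first on ties, in declared grid order) is refit on the full outer
training set and evaluated once on the outer test fold. Standardization
and shuffling happen inside each fold, on training rows only. One caveat is
inherent to windowed time-series CV: training windows that overlap a fold
boundary share a fraction of raw samples with the adjacent block; blocks
are contiguous so this affects boundary windows only, and the
chance-level-on-permuted-labels test guards against any exploitable
leakage.

Model families and grids: random forest (trees ∈ {50, 100, 200, 300},
depth ∈ {5, 10, 20, 30}, mtry = √p); SVM (sigmoid or RBF kernel,
regularization ∈ {1e−3, 1e−2, 1e−1, 1}, mapped to the cost parameter of
libsvm); k-NN (k ∈ {3, 5, 7, 9, 11}, Euclidean distance on standardized
features); MLP (five four-hidden-layer layouts from [128,128,128,128] to
[128,256,512,512], learning rate 1e−3). The MLP training protocol is
otherwise unspecified in the source setting, so the package fixes it:
full-batch Adam (β₁ = 0.9, β₂ = 0.999), ReLU hidden units, softmax
cross-entropy, seeded He initialization, at most 200 epochs with
early stopping — patience 20 on inner-validation BA when a validation set
is available (the inner CV loops), on the training-loss plateau otherwise
(outer refits). No installed R package fits multi-hidden-layer
perceptrons, so this network is implemented in-package in base R.

Determinism: every stochastic step (generator, shuffles, forest seeds, MLP
initialization) derives its seed from the master seed through a fixed
integer recurrence kept inside 32-bit range; identical inputs and seeds
give bit-identical reports. The rare k-NN vote tie is broken under a fixed
seed.

## Window-length sweep

Twenty lengths, linearly spaced with inclusive endpoints 0.05–1.0 s (step
0.05 s — the count and range are given, the spacing is our choice), overlap
always 20 % of the length. For each length the feature tables are rebuilt
from scratch and the forest is cross-validated with blockwise time folds in
which the test block is windowed without overlap and each surrounding
training block is windowed independently, so overlapping windows never
straddle into test material. When the sweep grid has several
hyperparameter points, selection inside a fold uses the forest's
out-of-bag error on that fold's training rows — an RF-native selector that
avoids a second nested loop at every (length × fold) cell. A length that
cannot give every fold at least one window per class is flagged unusable
rather than failing the sweep. The trade-off rule formalizes "highest BA at
the smallest window": the smallest usable length whose cross-session mean
BA is within `tolerance_pp` (default 2) percentage points of the best.

## Problem sizes

The default study conditions are three 60 s state segments, 32 channels
with 5 dead, neural sampling at 24 414 Hz — at the 0.55 s/0.11 s operating
point this yields 366 training windows of 288 features. The test suite
runs the forest's full grid at that size; the four-family comparison uses
a two-layout MLP grid, the chance-level suite uses an 8-channel, 15 s
session with 0.25 s windows, and the sweep checks use 8-channel, 15 s
sessions with 3 folds and a single-point forest grid. These reduced sizes
are the package's own choices for routine testing; all of them are stated
in the corresponding test files and in `scripts/acceptance.R`.

## Known limitations

* The generator's stationary, independent-channel Poisson model is a
  deliberately simple stand-in; none of its parameters are calibrated to
  real pudendal recordings.
* Contiguous-block CV with overlapping training windows retains a small
  boundary-sharing effect (see above).
* The SVM regularization candidates are interpreted as libsvm cost values;
  other software maps regularization strength inversely.
* Models are session-specific, as in the experimental setting; no
  cross-session or multi-subject transfer is implemented.
* The pipeline is offline; the causal-filter flag exists but real-time
  decoding (streaming windows, incremental standardization) is out of
  scope.
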