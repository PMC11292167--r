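---
title: "Methods: self-supervised mood-episode classification from wristband physiology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-supervised mood-episode classification from wristband physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wrist-worn devices such as the Empatica E4 record triaxial acceleration
(32 Hz), blood volume pulse (64 Hz), electrodermal activity (4 Hz), skin
temperature, heart rate and interbeat intervals during free-living wear. The
clinical question addressed here is binary: does a recording segment come from
a patient in an acute mood-disorder episode (depressive, manic or mixed) or
from a patient in euthymia? Expert labels are scarce, so the package pairs the
supervised classifier with two self-supervised pretraining schemes that learn
representations from unlabeled wear data and transfer them to the target task.

## Preprocessing model

Raw sessions pass through four deterministic stages, in this order:

1. **On/off-body detection.** A second is off-body iff any EDA sample in it is
   below 0.05 µS (loss of skin contact) or above the 100 µS sensor range, or
   any temperature sample leaves 30–40 °C. The rule is evaluated at 1-second
   resolution on the EDA/TEMP clock and broadcast to all channels by time
   interval; with multirate channels there is no unique sample-level
   correspondence, and a per-second decision is the coarsest unit on which all
   channels agree.
2. **Minimum wear run.** On-body runs shorter than 5 minutes are relabeled
   off-body ("at least" semantics: a 300-second run survives). The operation
   is idempotent.
3. **Sleep/wake scoring.** The arm elevation angle
   `atan(z / sqrt(x^2 + y^2))` is computed on 5-second epoch medians of each
   acceleration axis; an on-body period is sleep iff it lies in a maximal run
   of at least 5 minutes in which no successive-epoch angle change exceeds 5°.
   Design choice: an off-body gap *breaks* a sleep run rather than bridging
   it, because off-body samples carry no information about posture. A related
   open point was whether the wear-run rule should apply before or after sleep
   scoring; the package fixes the order off-body → minimum wear run → sleep,
   so sleep is only ever scored on wear periods already deemed trustworthy.
4. **Window slicing.** Each maximal wake span of length `L` seconds yields
   `floor((L - omega)/step) + 1` overlapping segments (defaults
   `omega = 512`, `step = 128` seconds); a segment never straddles a
   non-wake second. Segments inherit the recording label.

Channel-wise standardization `(x - mean)/max(SD, 1e-8)` uses **population**
SD computed on designated fitting data only — the target training split for
supervised runs, its aggregation with the unlabeled training split for
self-supervised runs. The epsilon guard maps constant channels to zero rather
than propagating division errors. Standardizing twice with the same statistics
is deliberately not the identity; the `scope` field of the statistics object
records provenance so leakage can be audited.

## Handcrafted features

For classical baselines each raw segment is summarized by 35 features:
per-axis and magnitude acceleration statistics (mean, SD, min, max, mean
squared energy, spectral entropy — Shannon entropy in nats of the normalized
power spectrum, DC bin excluded, defined as 0 for a constant signal); EDA
tonic/phasic summaries after a zero-phase 2nd-order Butterworth low-pass at
0.05 Hz (tonic = low-pass output, phasic = residual; phasic peaks are local
maxima with at least 0.01 µS prominence); HRV measures over the IBI events
inside the window (mean NN, SDNN, RMSSD, pNN50 with the standard 50 ms
threshold; flagged missing with fewer than two events); and temperature mean
and SD. This is a frozen, self-contained reduction of the much larger feature
sets produced by wearable toolkits: it keeps one representative per family
(time-domain accelerometry, tonic/phasic electrodermal activity, time-domain
HRV, temperature) so the classical baselines remain meaningful while every
feature has a closed-form definition that can be oracle-tested. Missing
values are mean-imputed with column means learned from training rows only.

## The multirate transformer

Each channel has its own embedding: a 1D convolution with kernel size equal
to the channel sampling rate, GELU, 1D batch normalization, then max pooling
with kernel and stride equal to the sampling rate. Convolutions use same
padding (a design choice; kernel and pool sizes alone do not fix the output
length), so every channel emits exactly one token per second — `omega` tokens
regardless of its rate — and the six channel embeddings concatenate along the
feature axis. A learned linear projection to `d_model` plus learned positional
embeddings feeds a post-norm transformer encoder (multi-head self-attention +
feed-forward blocks). Three interchangeable heads sit on top:

* **classify** — mean pooling over tokens (pooling over a CLS token was the
  other candidate; mean pooling is simpler and symmetric), a small MLP, and a
  softmax over {acute, euthymia}; trained with binary cross-entropy on the
  positive-class probability;
* **reconstruct** — a token-wise linear map back to `fs` samples per second
  per channel, giving native-length reconstructions for masked prediction;
* **transform_predict** — an MLP emitting six logits per channel.

The network, backpropagation and AdamW are implemented in the package itself
on base-R matrix operations with C++ kernels for the convolution, pooling and
GELU hot paths; every layer's analytic gradient is checked against central
finite differences in the unit suite. Training uses minibatch AdamW (decoupled
weight decay on weight matrices only) under a reduce-on-plateau schedule:
after 10 epochs without validation improvement the learning rate is multiplied
by 0.3, and training stops when a third reduction would be required; the
best-validation checkpoint is returned. Full-scale defaults follow the
published setup (batch 256, at most 300 epochs); the test suite uses a small
configuration (8 filters, `d_model` 64, 1–2 layers, 4 heads, batch 16) that
trains in minutes on one CPU core.

## Pretext tasks

**Masked prediction (MP).** Per channel, a Boolean mask of alternating runs is
sampled: masked-run lengths are geometric on {1, 2, ...} with mean `l0` (3 s,
converted to samples per channel — 96 samples at 32 Hz, 192 at 64 Hz),
unmasked runs geometric with mean `l1 = l0 (1 - r)/r`, which makes the
stationary masked fraction equal the ratio `r = 0.15`; the first run is masked
with probability `r`. Geometric support on {1, ...} with success probability
1/mean, and the first-run rule, follow the convention of masked-reconstruction
transformers for multivariate time series. Masked positions are zeroed and
the model minimizes RMSE over masked positions only.

**Transformation prediction (TP).** Per channel one of six transformations is
drawn uniformly — identity, Gaussian noise (SD 0.1 in standardized units),
magnitude warping (cubic-spline envelope, 4 interior knots, knot SD 0.2),
permutation (4 equal blocks shuffled), time warping (cubic-spline time remap,
4 knots, SD 0.2, resampled to the original length), cropping (a contiguous 50%
window stretched back by linear interpolation) — and the model minimizes the
channel-average categorical cross-entropy of guessing which transformation
each channel underwent. All transformations preserve length; identity is
bit-exact. Parameters are configurable; the defaults are common choices in the
signal-augmentation literature.

Transfer is either **linear readout** (encoder and batch-norm statistics
frozen — encoder outputs are bit-identical across target training, which the
tests assert — only a fresh classification head learns) or **fine-tuning**
(everything trainable from the pretrained initialization). Freezing batch-norm
statistics in linear readout is a deliberate choice: updating them would let
target data leak into the "frozen" feature extractor.

## Splits, metrics and statistics

Unlabeled recordings split 85:15 into pretraining train/validation sets at the
recording level (random under a seed; the assignment rule is otherwise
arbitrary). Labeled recordings are split 70:15:15 **along recording time**;
a segment belongs to a split only if its whole window lies inside the split's
time interval, so overlapping windows never leak across borders. Classes are
balanced by sorting each class's recordings by segment count, pairing
rank-to-rank (which minimizes the summed within-pair difference), and keeping
the first `n = min(pair counts)` segments of both members in temporal order.

Segment accuracy is the fraction of correctly classified segments. A
subject's prediction is the majority vote over its segments; the subject-level
probability is the mean of its segment probabilities. Exact vote ties (even
segment counts) are broken by that mean probability — the vote formula
presumes a strict majority, so some rule is required and the probability is
the natural arbiter. Model comparisons use (i) a paired t test on per-segment
correct-class probability differences, (ii) a random-intercept linear mixed
model of those differences with subject as the grouping factor (fixed
intercept tested against 0, Satterthwaite degrees of freedom), and (iii) a
paired t test on per-subject correct-vote fractions, all Bonferroni-corrected
with a configurable family size defaulting to 19. A constant difference vector
makes the t statistics degenerate; the comparison functions flag this (p = 1
when the difference is identically 0) instead of erroring.

The ablation harness pretrains on a reduced unlabeled collection — stratified
downsampling by dataset with at least one recording kept per retained dataset,
ratio 0 meaning the target training set alone, or leave-one-dataset-out — and
reports the accuracy change against the full-collection reference run with the
same initialization seed, isolating the data effect. The package also ships
published summary tables of such ablations at clinical scale
(`ablationReference()`); the correlation between unlabeled-data availability
and the accuracy change is recomputed from them with `pearsonCorr()`.

## The synthetic cohort generator

Real cohorts of this kind are access-restricted, so the generator produces
sessions with the structure the pipeline must exploit: per-channel baselines
plus circadian sinusoid plus AR(1) noise; acceleration as a gravity
orientation vector (constant during sleep, re-oriented roughly once a minute
during wake) plus movement noise; BVP as an amplitude-modulated oscillation at
the instantaneous pulse rate, from which IBI events and the HR channel derive;
nonwear hours with EDA below the 0.05 µS contact threshold and out-of-range
temperature. The two-class effect is parameterized (mean EDA shift in µS, a
multiplier on wake movement noise, a heart-rate shift in bpm) so tests can
sweep it from null to strong. Defaults: 8-hour sessions (long enough to
contain wear/nonwear and sleep/wake structure while staying desk-scale — the
clinical recordings motivating the design run ~48 h), hourly wear probability
0.9, sleep window hours 2–6, EDA shift 0.5 µS, activity scale 1.25, HR shift
5 bpm. The generator is seeded and bitwise reproducible, and its ground-truth
per-second status is recoverable (`trueStatus()`), which the structural
fidelity tests exploit (≥95% per-second agreement with the preprocessing
output at default noise).

What the generator does **not** emulate: motion artifacts in BVP, electrode
drift, medication effects, inter-subject physiological diversity beyond random
phases and orientations, or realistic sleep microstructure. Passing tests
therefore demonstrate that the machinery is correct and can recover planted
structure; they say nothing about clinical effect sizes on real patients.

## Numerical choices and problem sizes

* Population SD (divide by n) for standardization; guard `1e-8`.
* Masked RMSE is undefined for an empty mask; the loss errors rather than
  returning 0, so a silent no-op batch cannot occur.
* Max pooling breaks ties toward the earliest position; softmax rows are
  max-shifted for stability; cross-entropies clamp probabilities at `1e-12`.
* The end-to-end tests run a 6-subject, 1-hour-per-session cohort with
  64-second windows and a 1-layer model for 3–4 epochs: with a strong planted
  effect (EDA +1 µS, activity ×1.5, HR +10 bpm) the fine-tuned model recovers
  segment accuracy well above chance across 3 seeds, and with a null effect
  accuracy stays within binomial bounds of 50%. These sizes are the package's
  own desk-scale choices; the pipeline is the same at full scale, only the
  configuration objects change.
* Training is single-threaded deterministic under its seed: identical
  configurations reproduce loss histories bit-for-bit.

## Known limitations

The transformer is intentionally compact; no attempt is made to reproduce
tuned clinical-scale hyperparameters. Frequency-domain HRV, EDA deconvolution
and alternative sleep algorithms are out of scope. Classical baselines are
served through the feature matrix (any fit/predict learner can consume it);
the package does not wrap specific classical learners. Cross-subject
generalization (leave-subject-out) is deliberately not implemented — the
time-split protocol mirrors how personal-sensing systems are deployed, with
access to each subject's past data.
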