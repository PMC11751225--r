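---
title: "Interpretable residual shrinkage networks for single-channel EEG drowsiness detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable residual shrinkage networks for single-channel EEG drowsiness detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(drowsEEG)
```

# The problem

Drowsiness at the wheel is detectable in the occipital EEG: drowsy stretches
carry rhythmic theta–delta slow waves and transient alpha spindles, while
attentive wakefulness shows low-amplitude beta activity. The practical
setting this package targets is a single dry electrode (an occipital midline
channel) producing 3-second epochs at 128 Hz — 384 raw samples per decision —
and a classifier that must generalize to *subjects it has never seen*,
because calibrating per driver is unrealistic.

The package implements a compact one-dimensional residual shrinkage network
for this task together with the tooling around it: a label-smoothed,
weight-frozen training loop, leave-one-subject-out (LOSO) evaluation, a
class-activation interpretation method that projects decisions back onto the
raw waveform, two quantitative tests of heatmap quality, and a synthetic
multi-subject EEG generator that makes the whole pipeline exercisable at
desk scale.

# The model

## Feature extractor

A single convolution layer with 32 filters of length 64 (half the sampling
rate, so the filter bank can resolve rhythms above 2 Hz), stride 2, and
symmetric zero padding of 31 samples maps a 384-sample epoch to a 32 × 192
feature map. Batch normalization, a soft-shrink activation
(`y = sign(x) max(|x| − λ, 0)`, default λ = 0.5), and dropout (rate 0.5,
training only) complete the block. The stride-2 convolution alone accounts
for the halving of the temporal axis; there is no pooling layer. Padding of
31 per side is the unique symmetric choice that makes 384 map to exactly
192.

## Residual shrinkage unit

The core of the architecture is a residual block that *denoises its own
feature map with thresholds it learns per channel*. Two pointwise (1×1)
convolutions in pre-activation order (batch norm → rectifier → convolution,
the convention of the residual-shrinkage lineage in vibration diagnostics)
produce `U` (32 × 192). A squeeze-and-excitation branch turns each channel's
mean absolute activation `a_r = mean_i |U[r, i]|` into a scaling factor:

    z = W2 · relu(BN(W1 · a)),   σ = logistic(z) ∈ (0, 1),   τ_r = σ_r · a_r

so the soft threshold `τ_r` is always positive and can never exceed the
channel's own mean magnitude — shrinkage can silence noise but cannot zero a
whole channel. Soft thresholding `O = softThreshold(U, τ)` and an identity
shortcut give the block output `P = I + O`. In channel-wise (`CW`) mode each
channel gets its own threshold; the channel-shared (`CS`) variant collapses
σ to a scalar and uses the grand mean of `|U|`. `CW` is the default.

The bottleneck reduction ratio is 2 (32 → 16 → 32). With it, the full
channel-wise model has exactly

```{r}
countParameters(modelConfig())
```

trainable scalars — 5.6K after rounding — which is what fixed the reduction
ratio: it is the smallest standard choice whose total parameter ledger lands
on the published budget of this architecture class.

## Head, training, regularization

Global average pooling reduces `P` to 32 feature activations
`m_k = mean_j P[k, j]`; an affine head gives logits
`m_c = Σ_k w_{k,c} m_k + b_c` and a softmax the class probabilities.
Training minimizes label-smoothed cross entropy,

    Loss = − Σ_c [ 1{c=y} (1 − α) + α/C ] log p_c,   α = 0.1,

with Adam (learning rate 0.001, batch size 50). Two regularizers matter:

* **Weight freezing.** Before training, a uniform `[0,1]` matrix `K` with
  the shape of the head weight matrix is drawn once; entries with `K < t`
  (t = 0.2) are frozen — their gradients are masked on every update, so they
  are bit-identical before and after training. We binarize the mask rather
  than scaling updates continuously because frozen-parameter semantics
  ("cannot be updated") imply persistence; for the same reason the mask is
  drawn once per run, not per batch. The bias is never masked. The gradient
  masking is applied to the head weight gradient generally, so the contract
  survives label smoothing and any head loss.
* **Label smoothing** keeps the head from saturating its logits on the
  noisier drowsy/alert boundaries.

# Interpretation

Because the spatial (here: temporal) structure survives until the pooling
layer, the class activation map

    M_c(j) = Σ_k w_{k,c} P[k, j]

assigns each of the 192 feature-resolution timepoints a signed contribution
to the class logit; its temporal mean plus the head bias *is* the logit, an
identity the test suite checks to 1e-6. The map is z-scored (population
standard deviation; a constant map becomes all zeros) at length 192 first
and then each element is duplicated twice to restore input resolution 384 —
normalization before upsampling, because duplication would otherwise enter
the variance estimate. Visual evidence panels pair the colored waveform with
Welch relative band power (delta 1–4, theta 4–8, alpha 8–12, beta 12–30 Hz;
1-s Hann segments with 50% overlap — the standard convention, exposed as
arguments since the choice is not prescribed by the architecture).

Two quantitative heatmap checks are included:

* **Sensitivity test** — add a seeded sine-plus-noise perturbation
  `x + n·γ·RMS(x)·(sin(2πft + φ) + ξ)` at scales n = 1…5 (γ = 0.05, f = 5 Hz
  defaults), recompute the heatmap for 20 perturbed copies, and report the
  mean and best Pearson correlation with the unperturbed map per scale.
  RMS-relative amplitude keeps perturbed samples close to the original
  signal distribution. Both mean and max are reported because "best
  correlation across a perturbed batch" and "average correlation" are both
  defensible readings; plots default to the mean. Correlations are computed
  on z-scored maps.
* **Deletion test** — rank timepoints by heatmap value (descending, ties by
  time index so deletion sets are nested), zero the top fraction, and track
  the predicted probability of the labeled class. A sharp drop indicates the
  map found genuinely decision-relevant samples. Ranking operates on the
  upsampled 384-length map so ranks align one-to-one with input samples.

# The synthetic generator

The generator emulates the *structure* of the preprocessed driving-task
deposits this model family is evaluated on: multi-subject sets of 3-s
single-channel epochs, balanced or unbalanced per-subject class counts, and
class-discriminative oscillatory events. Its distributions are our own
construction, chosen to reproduce the qualitative waveform signatures that
serve as class evidence:

* background: unit-RMS pink (1/f) noise, the canonical broadband EEG
  spectrum;
* drowsy epochs: one or two events — theta–delta bursts (half-period
  frequency-jittered slow oscillation, 1.5–6 Hz) or alpha spindles
  (Hann-windowed tone at the subject's peak alpha frequency) — of 0.5–1.5 s
  at amplitude `burstSNR` (default 2) times the background RMS;
* alert epochs: a sustained beta rhythm (15–25 Hz, amplitude 1× background
  RMS) plus, with probability 0.1, a blink-like monophasic peak. Blinks are
  placed in *alert* epochs deliberately: a classifier that leans on ocular
  artifacts would be exploiting exactly the shortcut the interpretation
  method should expose;
* subject variability: lognormal gain (log-SD 0.2), peak alpha frequency
  uniform on 9–11 Hz, lognormal background level jitter (log-SD 0.1);
* unbalanced mode draws per-subject alert:drowsy ratios log-uniformly from
  0.3–5.5, the range spanned by the published per-subject counts of the real
  unbalanced deposit.

Every injected event is recorded with its interval and kind, which is what
makes localization scoring of the heatmaps possible.

What the generator does **not** emulate: 1/f-exponent variation,
non-stationary background, real artifact morphology (EMG, electrode pops),
volume-conduction mixtures, or label noise from reaction-time thresholding.
Passing the synthetic recovery tests therefore demonstrates that the
implementation learns and localizes the intended class evidence under
controlled conditions — not that it attains any particular accuracy on real
recordings.

# Evaluation protocol

`losoCV()` holds out one subject per fold and trains on all others,
asserting the partition properties (disjointness, coverage, subject
exclusion) on every run. It accepts either a single pool or a train/test
pool pair with identical subject sets — the published protocol trains on a
balanced pool while testing each held-out subject's unbalanced epochs.
Accuracy and the F1 score of the drowsy class are reported per fold and
averaged; F1 uses drowsy as the positive class (binary, not macro — the
choice is stated here because published tables leave it ambiguous) with a
zero-division guard returning 0.

# Numerical choices

* Batch normalization: population statistics within a batch, running
  averages (momentum 0.1, eps 1e-5, unbiased variance in the running
  estimate) at evaluation; evaluation mode is therefore deterministic and
  the interpretation path always runs in evaluation mode. Batches of size 1
  are skipped during training (batch statistics would be degenerate).
* Initialization: He-uniform for weights and biases; batch-norm scale 1,
  shift 0. All randomness — initialization, freeze mask, shuffling, dropout
  — derives from one seed, and every seeded helper restores the caller's RNG
  stream.
* Loss probabilities are clipped at 1e-12.
* The z-score guard maps constant heatmaps to zero; the Pearson correlation
  guard returns 0 with a warning on constant inputs.
* Two engines compute the same network: a plain-R reference implementation
  and a fused C++ (RcppArmadillo) engine used by the exported functions. The
  test suite checks them against each other to 1e-10 and the backward pass
  against finite differences; training runs the C++ engine with R's RNG so
  results are reproducible from the seed alone.

# Problem sizes used by the test suite

The shipped tests exercise the full default study conditions: 8 subjects ×
200 epochs for LOSO recovery (10 training epochs, five seeds), a reduced
4-subject LOSO protocol (120 epochs per subject, all folds averaged over
three seeds) for the burst-SNR difficulty dial — averaging over every
held-out subject rather than a single one keeps the dial's variance well
below its effect size, 50 drowsy samples for localization scoring, and
100–200 correctly classified samples for the sensitivity and deletion tests.
These sizes are the package's chosen desk-scale conditions; the functions
themselves scale to arbitrarily larger sets.

# Limitations

* Single-channel input only; no multi-channel montages.
* The published accuracy tables on the real driving-task deposits require
  downloading those deposits; `loadDeposit()` reads them after a one-time
  plain-text conversion (`scripts/convert_deposit.py`), with the occipital
  channel index supplied by the user, since neither the accession nor the
  channel order is part of this package.
* The network is small by design (5.6K parameters); it is a detector for a
  specific bi-state protocol, not a general sleep stager.
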