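# drowsEEG

Cross-subject drowsiness detection from raw single-channel EEG, with
built-in interpretation of *what* the classifier saw.

Drowsy driving shows up in the occipital EEG as theta–delta slow-wave
bursts and alpha spindles; attentive wakefulness as low-amplitude beta
activity. `drowsEEG` implements a compact one-dimensional **residual
shrinkage network** that classifies 3-second, 384-sample epochs
(128 Hz, one occipital channel) as alert or drowsy and generalizes across
subjects under leave-one-subject-out (LOSO) evaluation. It is aimed at
researchers working on portable single-channel EEG monitoring who need a
classifier whose decisions can be audited sample-by-sample.

## The model

A stride-2 convolution (32 filters of length 64, symmetric padding 31)
followed by batch norm, a soft-shrink activation and dropout maps an epoch
`x ∈ R^384` to a feature map `I ∈ R^{32×192}`. A residual unit then
denoises its own features with **learned per-channel soft thresholds**: two
pre-activation 1×1 convolutions produce `U`; a squeeze-and-excitation
bottleneck turns each channel's mean absolute activation
`a_r = mean_i |U_{i,r}|` into a scaling factor `σ_r ∈ (0,1)`, giving

    τ_r = σ_r · a_r ,   O = softThreshold(U, τ) ,   P = I + O .

Global average pooling `m_k = mean_j P_{k,j}` and an affine head
`m_c = Σ_k w_{k,c} m_k + b_c` give the class logits. Training minimizes
label-smoothed cross entropy (α = 0.1) with Adam (lr 0.001, batch 50) under
**weight freezing**: a fixed random 20% of head weights are masked out of
every gradient update. The full model has 5,554 trainable parameters
(≈ 5.6K).

Because temporal structure survives until the pooling layer, the class
activation map `M_c(j) = Σ_k w_{k,c} P_{k,j}` attributes the decision to
individual timepoints; z-scored and duplicated ×2 back to 384 samples it
overlays directly on the raw waveform. Perturbation-sensitivity (Pearson
correlation of heatmaps under seeded sine-plus-noise perturbations) and
deletion tests (probability drop when top-ranked samples are zeroed)
quantify heatmap quality, and a bundled multi-subject synthetic EEG
generator with ground-truth event annotations makes everything testable at
desk scale.

## Worked example

```r
library(drowsEEG)

es <- simulateEpochSet(syntheticSpec(nSubjects = 4, epochsPerClass = 60, seed = 1))
es
#> EpochSet: 480 epochs x 384 samples at 128 Hz (synthetic)
#>   subjects: 4 | alert: 240 | drowsy: 240
#>   annotated events: 592

net <- trainModel(subsetEpochs(es, subjectIds(es) != 4),
                  modelConfig(), trainConfig(nEpochs = 6, seed = 1))
net
#> DrowsyNet (CW thresholds): 32 filters, kernel 64, input 384 -> 192
#>   trainable parameters: 5554 | trained: TRUE
#>   final training loss: 0.5503 (6 epochs)

ev <- evaluateModel(net, subsetEpochs(es, subjectIds(es) == 4))
round(c(accuracy = ev$accuracy, f1 = ev$f1), 1)
#> accuracy       f1
#>     88.3     88.3
```

Subject 4 was never seen during training; 88.3% of its epochs are classified
correctly and the drowsy-class F1 matches because the confusion matrix is
symmetric here (7 misses per class out of 60). Interpretation of one drowsy
epoch:

```r
x  <- epochSignals(es)[which(epochLabels(es) == 1 & subjectIds(es) == 4)[1], ]
hm <- ecam(net, x, class = 1)      # 384-point contribution heatmap
round(hm$prob, 3)
#> [1] 0.657
bp <- relativeBandPower(x)
round(bp[1:4], 3)
#> delta theta alpha  beta
#> 0.665 0.200 0.044 0.091
```

The model assigns this epoch probability 0.657 of being drowsy;
`hm$upsampled` localizes the evidence (here a slow-wave burst — 86% of the
relative power sits in the delta–theta bands), and the generator's event
annotations (`epochEvents(es)`) let you score that localization exactly.

A command-line wrapper covers the same pipeline
(`inst/scripts/drowseeg simulate|train|evaluate|loso|explain|sensitivity|deletion|params`).
Real preprocessed deposits can be read with `loadDeposit()` after a
one-time conversion with `scripts/convert_deposit.py`.

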