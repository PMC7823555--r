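# p300vib

Detection of the P300 event-related potential in speller brain–computer
interfaces, using a convolutional network whose latent code is regularized by
a **variational information bottleneck (VIB)**.

## The problem

A P300 speller presents a 6×6 character matrix whose 6 rows and 6 columns
flash in random order. When the row or column containing the attended
character flashes (2 of every 12 intensifications), the EEG shows a positive
deflection peaking ≈300 ms after the stimulus — the P300. Spelling one
character therefore reduces to a binary classification of flash-locked EEG
epochs (P300 vs. non-P300), repeated over several presentation rounds, at a
notoriously low single-trial signal-to-noise ratio. The classifier's
difficulty is not only noise: most of the variance in a 64-channel × 160-sample
epoch is label-irrelevant background activity that an unconstrained network
happily overfits.

`p300vib` is aimed at BCI researchers who want a fully seeded, end-to-end
testbed for this problem: a synthetic oddball-paradigm simulator, the standard
preprocessing chain, the VIB detector, character decoding, and a β-sweep
harness that makes the information-restriction effect of the bottleneck
visible — all without requiring any external recordings.

## The model

An epoch `x` (channels × time) passes through a spatial convolution spanning
all channels (10 filters), a strided temporal convolution acting as filter and
sub-sampler (kernel 13, stride 13, 50 filters, tanh), and two fully connected
heads that parameterize a diagonal Gaussian posterior over a latent code `z`:

    p(z | x) = N(z; μ(x), diag(σ(x)²)),   σ = exp(σ̂)

Training samples the code with the reparameterization trick, `z = μ + σ ⊙ ε`,
`ε ~ N(0, I)`, applies dropout, and classifies with a sigmoid head
`y = f(w·(r∗z) + b)`. The loss is the variational bound on the information
bottleneck objective:

    Loss = (1/N) Σₙ [ E_{p(z|xₙ)} [−log q(yₙ|z)] + β · KL( p(z|xₙ) ‖ N(0, I) ) ]

with the KL in closed form, `−½ Σⱼ [1 + log σⱼ² − μⱼ² − σⱼ²]`. The weight `β`
prices the information flowing from the epoch into the code: too small and
label-irrelevant structure leaks through (overfitting), too large and the
posterior collapses onto the prior, blocking discriminative information too —
at the extreme the decoder falls to chance (1/36).

Characters are decoded by accumulating the detector's probabilities per flash
index over repetitions and taking the row argmax (indices 1–6) and column
argmax (indices 7–12); the decoded character sits at their intersection.

## Worked example

```r
library(p300vib)

## simulate a small speller session: 8 training and 6 test characters,
## 16 channels, 15 repetitions each, realistic noise (SD 1.5 vs amplitude 1)
scfg  <- syntheticConfig(nChannels = 16, noiseSD = 1.5, seed = 101)
train <- generateDataset(randomTargets(8, seed = 11), 15, scfg)
scfg2 <- syntheticConfig(nChannels = 16, noiseSD = 1.5, seed = 202)
test  <- generateDataset(randomTargets(6, seed = 22), 15, scfg2)
train
#> EpochSet: 1440 epoch(s), 16 channel(s) x 160 sample(s) @ 240 Hz
#>   labels : 240 positive / 1200 negative
#>   trials : 8 character(s)
#>   preproc: windowed

## preprocess: 0.1-20 Hz Chebyshev bandpass, per-sample normalization,
## class rebalancing (training data only)
pc     <- preprocessConfig()
trainP <- preprocessEpochs(train, pc, rebalance = TRUE)
testP  <- preprocessEpochs(test, pc)

## train the VIB network at beta = 0.01
vc    <- vibConfig(nChannels = 16, nSpatialFilters = 4, nTemporalFilters = 10,
                   latentDim = 16, beta = 0.01, seed = 1)
model <- trainVIB(trainP, vc, trainConfig(nPasses = 8, seed = 1))
model
#> VIBModel: 16 x 160 input -> 4 spatial, 10 temporal filters -> J = 16
#>   beta = 0.01  dropout p = 0.5
#>   trained: 8 pass(es), final loss 0.2796

## decode the attended characters from 1, 5, 10 and 15 repetitions
evaluateCharacterAccuracy(model, testP, c(1, 5, 10, 15))
#>   repetitions nCorrect nTrials accuracy
#> 1           1        6       6      100
#> 2           5        6       6      100
#> 3          10        6       6      100
#> 4          15        6       6      100
```

All six attended characters are recovered at every repetition count: at this
channel count and training size the per-epoch detector is reliable enough
that even a single repetition (12 flashes, 2 informative) suffices, and
accumulation over repetitions only consolidates the margin. `betaSweep()`
runs the same experiment across a grid of β values and additionally reports
the mean per-sample KL — the information actually admitted through the
bottleneck, which collapses towards 0 as β grows large.

A command-line wrapper with the same functionality (subcommands `simulate`,
`preprocess`, `train`, `evaluate`, `sweep-beta`, each writing a JSON run log)
is installed at `system.file("scripts", "p300vib", package = "p300vib")`.

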