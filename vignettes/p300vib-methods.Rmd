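---
title: "Methods: the VIB speller detector, its simulator and its numerics"
author: "p300vib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the VIB speller detector, its simulator and its numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, the numerical choices, and the design
decisions that were genuinely open. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## 1. The paradigm and the decoding rule

The speller presents a 6×6 matrix of 36 distinct characters. Flash indices
follow the convention that `i` in 1..6 denotes row `i` and `i` in 7..12
denotes column `i − 6`. One *repetition* flashes each of the 12 indices
exactly once in uniform-random order (`buildFlashSchedule()`); exactly 2 of
the 12 flashes intersect the attended character, so 15 repetitions yield 180
flash-locked epochs, 30 of them targets.

Decoding accumulates the detector's per-epoch P300 probability per flash
index over the first `k` repetitions and takes the argmax over 1..6 for the
row and over 7..12 for the column. Two conventions are deliberate:

* **Accumulation is a sum** of probabilities per index. The single-repetition
  decoding rule generalizes in several equivalent ways; the sum (equivalent
  to the mean for the argmax) is the standard speller accumulation.
* **Ties break to the lowest flash index.** Ties occur with probability zero
  for continuous scores but matter for degenerate inputs (e.g. a constant
  detector); a deterministic rule keeps the decoder a total function, and the
  test suite checks its exact agreement with an exhaustive 36-cell search.

The default layout is row-major `A`–`Z`, `1`–`9`, `_`; any 36 distinct
characters may be supplied, since published interfaces differ in the last row.

## 2. The detection network

Epochs (channels × time) are encoded by:

1. **L1, spatial convolution** — a kernel spanning all channels at a single
   time point, i.e. a learned montage re-referencing; 10 filters, linear.
   A linear L1 keeps the layer interpretable as a pure spatial filter.
2. **L2, temporal convolution** — kernel 13 samples, stride 13, 50 filters,
   `tanh`. With stride equal to the kernel this layer is simultaneously a
   temporal filter and a sub-sampler; 160 samples yield 12 positions.
3. **Flatten + two linear heads** — emitting the latent Gaussian mean `μ` and
   log standard deviation `σ̂`, each of length `J = 64`.
4. **Reparameterized sampling** — `z = μ + exp(σ̂) ⊙ ε`, `ε ~ N(0, I)`, so the
   draw is a deterministic function of the parameters and independent noise
   and gradients flow through `μ` and `σ̂` only.
5. **Dropout + sigmoid head** — a Bernoulli keep mask (drop rate `p = 0.5`)
   on `z`, then a scalar affine map and sigmoid.

The loss is the mean binary cross-entropy of the sampled forward pass (one
Monte Carlo draw per input by default) plus `β` times the mean closed-form KL
divergence of the posterior from the standard normal prior,

$$\mathrm{KL} = -\tfrac12 \sum_{j=1}^{J}\left[1 + \log\sigma_j^2 - \mu_j^2 -
\sigma_j^2\right],\qquad \sigma_j = e^{\hat\sigma_j}.$$

**The σ̂ convention.** Writing the encoder's second head as the log *standard
deviation* (σ = e^σ̂) is the only reading under which the reparameterization
`z = μ + e^σ̂ ⊙ ε` and the KL above hold simultaneously; descriptions that
call e^σ̂ the "variance" are internally inconsistent with both. The package
adopts σ = e^σ̂ throughout, and verifies the closed form against numerical
quadrature to 1e-6.

**Architecture numerals.** The spatial/temporal filter counts and kernel
sizes (10; 13/13; 50) follow the classic convolutional P300 detector this
architecture extends; the published description of the VIB variant does not
print legible values for them, so they are exposed in `vibConfig()` and kept
at the classic defaults.

**Inference rule.** At decode time the latent is set to its posterior mean
(`ε = 0`), dropout is off, and the head weights are rescaled by the keep
probability `1 − p` (the standard dropout expectation convention; training
applies the raw mask). Deterministic inference makes decoding reproducible;
the sigmoid's nonlinearity means this is *not* the limit of averaged
stochastic passes, and no such claim is tested.

**Gradients and optimization.** Backpropagation through all layers is
implemented analytically in matrix algebra and checked against central finite
differences (relative error ≤ 1e-4 on a frozen-noise tiny network; observed
orders of magnitude tighter). Training uses the adaptive-moment SGD variant
(Adam, rate 1e-3, batch 64) — the published method specifies only
"stochastic gradient descent", so the optimizer is a config choice. All
randomness (initialization, shuffling, latent draws, dropout masks) is
seeded; identical configurations reproduce bit-identical loss histories.
Training fails loudly (never silently) on a non-finite loss. An optional
validation set enables early stopping on the validation loss with a patience
counter; rebalancing must be applied *after* any train/validation split and
to the training side only, to avoid duplicate leakage.

## 3. Preprocessing

The chain is, in order: window → filter → normalize → rebalance.

| Step | Default | Notes |
|---|---|---|
| Window | 0–670 ms post flash | `floor(duration·fs)` = 160 samples at 240 Hz; 0-based, half-open `[start, end)` |
| Bandpass | Chebyshev I, order parameter 4, 0.1–20 Hz, 0.5 dB ripple | causal single pass by default |
| Normalize | zero mean, unit variance | over all channel×time entries of a sample (population variance) |
| Rebalance | duplicate positives ×4 | 30/150 → 150/150; training data only |

Open choices, resolved as follows:

* **Filter application**: causal single-pass, matching how an online speller
  would run; zero-phase forward–backward filtering is available behind
  `zeroPhase = TRUE`. Passing `n = 4` to the bandpass designer yields an
  order-8 transfer function — the convention of the MATLAB-era BCI
  toolchains whose published pipelines this follows.
* **Ripple**: a Chebyshev type-I design requires a ripple figure; 0.5 dB is
  the common default and is exposed in the config.
* **Normalization scope**: whole-sample ("every sample" normalized), with a
  per-channel variant behind `perChannelNorm = TRUE`. Zero-variance epochs
  raise a degenerate-input error rather than dividing by zero.

A numerical caveat: the 0.1 Hz lower edge puts the recursion's poles at
|z| ≈ 0.9996, so double-precision roundoff is amplified by roughly
1/(1−|z|). Identities that are exact in exact arithmetic (e.g. linearity)
hold to ~1e-6 relative here, not machine precision; the tests assert them at
that level and cross-check the implementation against an independent filter
routine at 1e-9 on identical inputs.

## 4. The synthetic oddball generator

`generateTrial()`/`generateDataset()` emulate the benchmark speller
recordings so that every downstream stage is testable without external data:

* **Geometry**: 64 channels, 240 Hz, 160-sample epochs (configurable).
* **Target deflection**: a non-negative Gaussian bump peaking 300 ms post
  flash (SD 100 ms, amplitude 1), evaluated in continuous time at a latency
  jittered per epoch (SD 20 ms). Under Gaussian jitter the expected peak is
  attenuated by exactly $w/\sqrt{w^2+j^2}$, which the Monte Carlo tests use
  as their oracle.
* **Topography**: a centro-parietal-like Gaussian bump across the channel
  axis (centred at 60 % of the montage, width a tenth of it), weights in
  [0, 1] — effectively a contiguous third of the channels carry the signal.
* **Noise**: per-channel Gaussian background at SD 1.5, half of the variance
  white and half pink (1/f-shaped above 1 Hz, no DC), mixed by variance
  share. Single-trial P300 amplitudes are well below the background in real
  recordings; SD 1.5 against amplitude 1 puts the simulator in that regime
  while remaining learnable at desk scale.
* **Nuisance**: a 10 Hz sinusoid of amplitude 1, common to all channels,
  with an independent uniform phase per epoch and present in targets and
  non-targets alike — deliberately label-irrelevant structured interference
  inside the passband, the kind of signal the bottleneck is meant to block.

What the generator does **not** emulate: real electrode covariance and
volume conduction, eye/muscle artifacts, non-stationarity across the session,
refractory effects when target flashes fall close together, and
subject-specific P300 morphology. Passing tests on this simulator therefore
demonstrate the correctness and the qualitative behavior of the pipeline
(accumulation gains, bottleneck collapse), not clinical-grade performance on
competition recordings, whose printed accuracies are intentionally not
reproduced here.

Determinism: every trial derives its own 31-bit seed from the master seed via
a fixed Lehmer-style mix, so datasets are bit-reproducible and trials are
independent.

## 5. Experiment scales used by the tests and acceptance script

Problem sizes are chosen so the whole suite runs comfortably on one CPU:

* Unit tests run a 4-channel, 32-sample geometry with a matching reduced
  network; gradient checks use a J = 2 network with frozen noise.
* The end-to-end benchmark runs 16 channels with full 160-sample epochs:
  8 training / 6 test characters at noise SD 0.3 ("high SNR") for the
  accuracy-versus-repetitions experiment (5 seeds), and 12 training
  characters at the default noise SD 1.5 for the β-collapse experiment
  (β = 0.01 vs β = 100, 3 seeds), with a 4/10-filter, J = 16 network trained
  for 8 passes.
* `scripts/acceptance.R` re-runs both benchmarks once from the CLI seed and
  recomputes all paradigm counts on full-size (where geometry matters) or
  8-channel (where only counts matter) simulations.

## 6. Known limitations

* The network is implemented in base R matrix algebra; it is sized for the
  speller problem (10^4–10^5 parameters) and is not a general deep-learning
  engine. Very large latent sizes or batch counts will be slow.
* `mcSamples > 1` uses a dense collapse matrix per batch; it is intended for
  estimator-accuracy studies at small batch sizes, not routine training.
* The competition-format loader reads the released MATLAB layout through the
  system python's scipy when given a `.mat` path (or natively from an `.rds`
  of the same structure); it is plumbing for users who hold those recordings
  and is not exercised by the benchmarks.
* Early stopping restores the best validation parameters only when a
  validation set is supplied; the default configuration trains for a fixed
  number of passes.
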