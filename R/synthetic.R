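#' @include container.R speller.R
NULL

# Default centro-parietal-like topography: a Gaussian bump across the channel
# axis centred at 60% of the montage, effectively covering a contiguous third
# of the channels, peak weight 1.
defaultSpatialProfile <- function(nChannels) {
  ch <- seq_len(nChannels)
  centre <- 0.6 * nChannels
  width <- nChannels / 10
  exp(-0.5 * ((ch - centre) / width)^2)
}

#' Configure the synthetic oddball EEG generator
#'
#' Defaults emulate the benchmark speller recordings: 64 channels at 240 Hz,
#' 160-sample epochs, a target deflection peaking 300 ms post flash with 20 ms
#' latency jitter, background noise at 1.5 signal units (half white, half
#' pink) against a unit-amplitude deflection — a realistically low single-trial
#' SNR — plus a unit-amplitude 10 Hz sinusoidal nuisance common to target and
#' non-target epochs.
#'
#' @param nChannels,fs,epochLen epoch geometry (see [SyntheticConfig-class]).
#' @param p300Latency,p300Width,p300Amplitude deflection shape parameters.
#' @param latencyJitterSD per-epoch latency jitter SD in seconds.
#' @param noiseSD,pinkFraction background noise level and its 1/f share.
#' @param spatialProfile per-channel deflection weights in [0, 1].
#' @param nuisanceAmplitude,nuisanceFreq shared label-irrelevant sinusoid.
#' @param seed master seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nChannels = 64L, fs = 240, epochLen = 160L,
                            p300Latency = 0.300, p300Width = 0.100,
                            p300Amplitude = 1, latencyJitterSD = 0.02,
                            noiseSD = 1.5, pinkFraction = 0.5,
                            spatialProfile = defaultSpatialProfile(nChannels),
                            nuisanceAmplitude = 1, nuisanceFreq = 10,
                            seed = 1L) {
  new("SyntheticConfig", nChannels = as.integer(nChannels), fs = fs,
      epochLen = as.integer(epochLen), p300Latency = p300Latency,
      p300Width = p300Width, p300Amplitude = p300Amplitude,
      latencyJitterSD = latencyJitterSD, noiseSD = noiseSD,
      pinkFraction = pinkFraction, spatialProfile = spatialProfile,
      nuisanceAmplitude = nuisanceAmplitude, nuisanceFreq = nuisanceFreq,
      seed = as.integer(seed))
}

#' The P300-like target waveform
#'
#' A non-negative unimodal Gaussian bump over the epoch, peaking at sample
#' round(p300Latency * fs) (0-based) with peak value p300Amplitude.
#'
#' @param config a [SyntheticConfig-class].
#' @return numeric waveform of length \code{epochLen}.
#' @export
p300Template <- function(config) {
  peak <- round(config@p300Latency * config@fs)
  if (peak < 0 || peak > config@epochLen - 1L)
    stop("invalid argument: p300Latency falls outside the epoch window",
         call. = FALSE)
  t <- seq_len(config@epochLen) - 1L
  config@p300Amplitude *
    exp(-0.5 * ((t - peak) / (config@p300Width * config@fs))^2)
}

# Template evaluated in continuous time at a jittered latency (no sample
# rounding), so the expected peak attenuation under Gaussian jitter has the
# closed form w / sqrt(w^2 + j^2).
jitteredTemplate <- function(config, jitter) {
  t <- (seq_len(config@epochLen) - 1L) / config@fs
  config@p300Amplitude *
    exp(-0.5 * ((t - config@p300Latency - jitter) / config@p300Width)^2)
}

# Unit-variance pink (1/f amplitude) noise, one column per channel, shaped in
# the frequency domain from white Gaussian input.
pinkNoise <- function(nSamples, nCols, fs) {
  white <- matrix(rnorm(nSamples * nCols), nSamples, nCols)
  freqs <- c(0, seq_len(nSamples - 1L)) * fs / nSamples
  freqs <- pmin(freqs, fs - freqs)            # two-sided spectrum
  amp <- 1 / sqrt(pmax(freqs, 1))             # flat below 1 Hz, 1/f above
  amp[1L] <- 0                                # no DC drift
  amp <- amp / sqrt(mean(amp^2))              # unit variance by construction
  shaped <- stats::mvfft(white) * amp
  Re(stats::mvfft(shaped, inverse = TRUE)) / nSamples
}

# Background noise + shared nuisance for all N epochs of a trial at once
# (channels x time x N). White and pink components are mixed by variance
# share; the nuisance sinusoid has an independent uniform phase per epoch and
# is common to all channels.
trialNoise <- function(config, N) {
  C <- config@nChannels; L <- config@epochLen
  wf <- sqrt(1 - config@pinkFraction); pf <- sqrt(config@pinkFraction)
  noise <- wf * array(rnorm(C * L * N), c(C, L, N))
  if (pf > 0) {
    pk <- pinkNoise(L, C * N, config@fs)             # L x (C*N)
    noise <- noise + pf * aperm(array(pk, c(L, C, N)), c(2L, 1L, 3L))
  }
  noise <- config@noiseSD * noise
  if (config@nuisanceAmplitude > 0) {
    t <- (seq_len(L) - 1L) / config@fs
    phases <- runif(N, 0, 2 * pi)
    wave <- config@nuisanceAmplitude *
      sin(2 * pi * config@nuisanceFreq * outer(t, rep(1, N)) +
            outer(rep(1, L), phases))                # L x N
    noise <- noise + aperm(array(wave, c(L, N, C)), c(3L, 1L, 2L))
  }
  noise
}

#' Simulate one speller character trial
#'
#' Generates 12 * nRepetitions flash-locked epochs in presentation order: a
#' randomized flash schedule per repetition, the spatially weighted, latency-
#' jittered P300 deflection added on the two target flashes of each
#' repetition, and background noise plus the shared nuisance on every epoch.
#' Deterministic given \code{config@seed}.
#'
#' @param target the attended character.
#' @param nRepetitions repetitions of the 12 flashes (the paradigm uses 15).
#' @param config a [SyntheticConfig-class].
#' @param matrix the [SpellerMatrix-class].
#' @return an [EpochSet-class] with labels and the target in its metadata.
#' @export
generateTrial <- function(target, nRepetitions = 15L,
                          config = syntheticConfig(),
                          matrix = spellerMatrix()) {
  nRepetitions <- assertCount(nRepetitions, "nRepetitions")
  charPosition(matrix, target)                 # validates the target
  p300Template(config)                         # validates the latency/window
  withSeed(config@seed, {
    schedule <- buildFlashSchedule(nRepetitions,
                                   seed = sample.int(.Machine$integer.max, 1L))
    labels <- labelEpochs(schedule, target, matrix)
    fi <- flashSequence(schedule)
    N <- 12L * nRepetitions
    arr <- trialNoise(config, N)
    pos <- which(labels == 1L)
    if (config@p300Amplitude != 0 && length(pos)) {
      jit <- if (config@latencyJitterSD > 0)
        rnorm(length(pos), 0, config@latencyJitterSD) else numeric(length(pos))
      for (k in seq_along(pos))
        arr[, , pos[k]] <- arr[, , pos[k]] +
          outer(config@spatialProfile, jitteredTemplate(config, jit[k]))
    }
    EpochSet(arr, flashIndex = fi,
             repetitionIndex = rep(seq_len(nRepetitions), each = 12L),
             characterIndex = rep(1L, N), label = labels,
             fs = config@fs, layout = matrix, targets = target)
  })
}

#' Simulate a multi-character speller dataset
#'
#' Independent character trials with per-trial seeds derived deterministically
#' from the master seed, concatenated into one container.
#'
#' @param targets character vector of attended characters (e.g. 85 for a
#'   training set, 100 for a test set).
#' @param nRepetitions repetitions per character.
#' @param config a [SyntheticConfig-class]; \code{config@seed} is the master
#'   seed.
#' @param matrix the [SpellerMatrix-class].
#' @return an [EpochSet-class] covering all trials.
#' @export
generateDataset <- function(targets, nRepetitions = 15L,
                            config = syntheticConfig(),
                            matrix = spellerMatrix()) {
  if (length(targets) < 1L)
    stop("invalid argument: empty target sequence", call. = FALSE)
  trials <- lapply(seq_along(targets), function(i) {
    cfg <- config
    cfg@seed <- deriveSeed(config@seed, i)
    generateTrial(targets[i], nRepetitions, cfg, matrix)
  })
  bindEpochSets(trials)
}

#' Draw random attended characters
#'
#' Convenience helper for building benchmark datasets: uniformly random
#' characters from the speller matrix.
#'
#' @param n number of characters.
#' @param seed integer seed.
#' @param matrix the [SpellerMatrix-class].
#' @return character vector of length n.
#' @export
randomTargets <- function(n, seed = 1L, matrix = spellerMatrix()) {
  n <- assertCount(n, "n")
  withSeed(seed, sample(as.vector(matrix@layout), n, replace = TRUE))
}
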