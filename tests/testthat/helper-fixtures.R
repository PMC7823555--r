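# Shared fixture builders. Everything is generated in code; sizes are kept
# small so the whole suite runs quickly on one CPU.

# A reduced-geometry synthetic configuration used by most signal-path tests.
tinySynthConfig <- function(seed = 1L, nChannels = 4L, epochLen = 32L,
                            noiseSD = 0.5, latencyJitterSD = 0.005, ...) {
  syntheticConfig(nChannels = nChannels, epochLen = epochLen, fs = 240,
                  p300Latency = 0.05, p300Width = 0.02,
                  latencyJitterSD = latencyJitterSD, noiseSD = noiseSD,
                  seed = seed, ...)
}

# A reduced network matching tinySynthConfig geometry.
tinyVibConfig <- function(seed = 1L, beta = 0.01, ...) {
  vibConfig(nChannels = 4L, epochLen = 32L, nSpatialFilters = 2L,
            temporalKernel = 8L, temporalStride = 8L, nTemporalFilters = 4L,
            latentDim = 4L, beta = beta, seed = seed, ...)
}

# The scaled benchmark used by the end-to-end and beta-sweep suites:
# full 160-sample epochs at 240 Hz, 16 channels.
benchSynthConfig <- function(seed, noiseSD = 1.5) {
  syntheticConfig(nChannels = 16L, noiseSD = noiseSD, seed = seed)
}

benchVibConfig <- function(seed, beta = 0.01) {
  vibConfig(nChannels = 16L, nSpatialFilters = 4L, nTemporalFilters = 10L,
            latentDim = 16L, beta = beta, seed = seed)
}

# Simulate, preprocess and split one benchmark run; returns the trained model
# and its evaluation table.
benchRun <- function(seed, noiseSD, beta = 0.01, nTrain = 8L, nTest = 6L,
                     passes = 8L) {
  pc <- preprocessConfig()
  strain <- benchSynthConfig(seed, noiseSD)
  stest <- benchSynthConfig(seed + 5000L, noiseSD)
  train <- generateDataset(randomTargets(nTrain, seed), 15L, strain)
  test <- generateDataset(randomTargets(nTest, seed + 77L), 15L, stest)
  trainP <- preprocessEpochs(train, pc, rebalance = TRUE)
  testP <- preprocessEpochs(test, pc)
  model <- trainVIB(trainP, benchVibConfig(seed, beta),
                    trainConfig(nPasses = passes, seed = seed))
  list(model = model, testP = testP,
       acc = evaluateCharacterAccuracy(model, testP, c(1L, 5L, 10L, 15L)))
}

# Mean per-sample KL of the encoder posterior over a dataset.
meanKL <- function(model, epochs) {
  enc <- encode(model, epochs)
  mean(0.5 * colSums(enc$mu^2 + exp(2 * enc$logScale) - 1 - 2 * enc$logScale))
}

# Independent single-dimension KL oracle: numerical quadrature of
# KL(N(mu, sigma^2) || N(0,1)).
klQuadrature <- function(mu, logScale) {
  sum(mapply(function(m, s) {
    sd <- exp(s)
    stats::integrate(function(z)
      stats::dnorm(z, m, sd) *
        (stats::dnorm(z, m, sd, log = TRUE) - stats::dnorm(z, log = TRUE)),
      m - 12 * sd, m + 12 * sd, rel.tol = 1e-10)$value
  }, mu, logScale))
}

# Brute-force character decoder: scores every one of the 36 cells by
# y[row] + y[col + 6] and picks the row-major first maximum.
bruteForceDecode <- function(y, m = spellerMatrix()) {
  best <- -Inf; bestChar <- NULL
  for (r in 1:6) for (co in 1:6) {
    s <- y[r] + y[co + 6L]
    if (s > best + 1e-12) { best <- s; bestChar <- charAt(m, r, co) }
  }
  bestChar
}

# A hand-built network that detects the sign of a constant epoch perfectly:
# used to drive the decoding pipeline with near-perfect probabilities.
perfectSignModel <- function() {
  cfg <- vibConfig(nChannels = 1L, epochLen = 8L, nSpatialFilters = 1L,
                   temporalKernel = 8L, temporalStride = 8L,
                   nTemporalFilters = 1L, latentDim = 1L, beta = 0,
                   dropout = 0, seed = 1L)
  m <- initVIBModel(cfg)
  m@params <- list(W1 = matrix(1, 1, 1), b1 = 0,
                   W2 = matrix(1 / 8, 1, 8), b2 = 0,
                   Wmu = matrix(10, 1, 1), bmu = 0,
                   Wsig = matrix(0, 1, 1), bsig = -10,
                   wout = 10, bout = 0)
  m
}

# Epochs for perfectSignModel: constant +1 on target flashes, -1 elsewhere.
signEpochSet <- function(targets, nRepetitions = 3L, seed = 11L) {
  m <- spellerMatrix()
  parts <- lapply(seq_along(targets), function(i) {
    sch <- buildFlashSchedule(nRepetitions, seed = seed + i)
    lab <- labelEpochs(sch, targets[i], m)
    arr <- array(rep(ifelse(lab == 1L, 1, -1), each = 8L),
                 c(1L, 8L, length(lab)))
    EpochSet(arr, flashIndex = flashSequence(sch),
             repetitionIndex = rep(seq_len(nRepetitions), each = 12L),
             label = lab, fs = 240, targets = targets[i])
  })
  bindEpochSets(parts)
}

# Minimal continuous session in the competition's released layout.
syntheticSession <- function(targets = c("A", "O", "9"), nRepetitions = 2L,
                             nChannels = 3L, seed = 21L) {
  m <- spellerMatrix()
  flashOn <- 24L; gap <- 18L; fs <- 240
  nFlash <- 12L * nRepetitions
  nSamp <- nFlash * (flashOn + gap) + 200L
  nChar <- length(targets)
  set.seed(seed)
  Signal <- array(rnorm(nChar * nSamp * nChannels), c(nChar, nSamp, nChannels))
  Flashing <- StimulusCode <- StimulusType <- array(0, c(nChar, nSamp))
  for (ch in seq_len(nChar)) {
    sch <- buildFlashSchedule(nRepetitions, seed = seed + ch)
    codes <- flashSequence(sch)
    hits <- targetFlashIndices(m, targets[ch])
    for (k in seq_len(nFlash)) {
      on <- (k - 1L) * (flashOn + gap) + 1L
      idx <- on:(on + flashOn - 1L)
      Flashing[ch, idx] <- 1
      StimulusCode[ch, idx] <- codes[k]
      StimulusType[ch, idx] <- as.numeric(codes[k] %in% hits)
    }
  }
  list(Signal = Signal, Flashing = Flashing, StimulusCode = StimulusCode,
       StimulusType = StimulusType, TargetChar = paste(targets, collapse = ""))
}
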