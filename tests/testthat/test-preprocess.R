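test_that("the 0-670 ms window at 240 Hz yields 64 x 160 epochs", {
  pc <- preprocessConfig()
  expect_equal(windowSamples(pc), 160L)
  rec <- matrix(rnorm(64 * 2000), 64)
  ep <- extractWindow(rec, c(0L, 500L, 1000L), pc)
  expect_equal(dim(epochSignals(ep, 1)), c(64L, 160L))
  expect_equal(ncol(ep), 3L)
  # identity slice: onset 0 returns the first window verbatim
  expect_equal(epochSignals(ep, 1), rec[, 1:160])
  expect_equal(epochSignals(ep, 2), rec[, 501:660])
  expect_error(extractWindow(rec, c(0L, 1900L), pc),
               "onset 1900 too close")
})

test_that("the designed bandpass matches its analytic frequency response", {
  pc <- preprocessConfig()
  # passband: within the 0.5 dB ripple of unit gain
  rippleFloor <- 10^(-pc@passbandRippleDb / 20)
  gains <- bandpassResponse(pc, c(1, 5, 10, 15))
  expect_true(all(gains >= rippleFloor - 1e-6 & gains <= 1 + 1e-6))
  # stopband: strong attenuation at mains frequency
  expect_lt(bandpassResponse(pc, 60), 0.1)
  expect_lt(bandpassResponse(pc, 0.01), 0.1)
  # steady-state sinusoid gain agrees with the analytic response in the
  # passband, and is strongly attenuated in the stopband
  fs <- pc@fs
  t <- (0:(fs * 60 - 1)) / fs
  tail2s <- (length(t) - 2 * fs):length(t)
  y10 <- bandpassFilter(matrix(sin(2 * pi * 10 * t), 1), pc)
  expect_equal(max(abs(y10[1, tail2s])), bandpassResponse(pc, 10),
               tolerance = 0.02)
  expect_gt(max(abs(y10[1, tail2s])), rippleFloor - 0.02)
  y60 <- bandpassFilter(matrix(sin(2 * pi * 60 * t), 1), pc)
  expect_lt(max(abs(y60[1, tail2s])), 0.1)
})

test_that("filtering is linear, shape-preserving and matches signal::filter", {
  pc <- preprocessConfig()
  set.seed(31)
  X <- matrix(rnorm(4 * 160), 4)
  Y <- matrix(rnorm(4 * 160), 4)
  expect_equal(bandpassFilter(X * 0, pc), X * 0)
  # linear to machine precision amplified by the recursion: the 0.1 Hz edge
  # puts poles at |z| ~ 0.9996, so roundoff grows by ~1/(1-|z|) through the
  # filter; 1e-6 relative is the attainable double-precision bound here
  lhs <- bandpassFilter(2.5 * X - 1.3 * Y, pc)
  rhs <- 2.5 * bandpassFilter(X, pc) - 1.3 * bandpassFilter(Y, pc)
  expect_equal(lhs, rhs, tolerance = 1e-6)
  expect_equal(dim(bandpassFilter(X, pc)), dim(X))
  # independent route: the signal package's own causal filter
  flt <- signal::cheby1(pc@filterOrder, pc@passbandRippleDb,
                        c(pc@bandLow, pc@bandHigh) / (pc@fs / 2), type = "pass")
  ref <- t(apply(X, 1, function(ch) as.numeric(signal::filter(flt, ch))))
  expect_equal(bandpassFilter(X, pc), ref, tolerance = 1e-9)
  expect_error(bandpassFilter(matrix(c(1, Inf, rnorm(158 * 2 - 2)), 2), pc),
               "non-finite")
  expect_error(bandpassFilter(matrix(rnorm(8), 2, 4), pc), "too short")
})

test_that("per-sample normalization gives zero mean, unit variance", {
  set.seed(32)
  for (i in 1:50) {
    x <- matrix(rnorm(6 * 40, sd = runif(1, 0.1, 10)), 6)
    z <- normalizeEpochs(x)
    expect_lt(abs(mean(z)), 1e-9)
    expect_lt(abs(mean((z - mean(z))^2) - 1), 1e-9)
    # idempotence and affine invariance
    expect_equal(normalizeEpochs(z), z, tolerance = 1e-9)
    expect_equal(normalizeEpochs(3.7 * x + 2), z, tolerance = 1e-9)
  }
  expect_error(normalizeEpochs(matrix(5, 4, 8)), "degenerate input")
  # per-channel variant
  pc <- preprocessConfig(perChannelNorm = TRUE)
  z <- normalizeEpochs(matrix(rnorm(6 * 40), 6), pc)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_true(all(abs(rowMeans(z^2) - 1) < 1e-9))
})

test_that("rebalancing duplicates positives bit-exactly, negatives untouched", {
  cfg <- tinySynthConfig(seed = 7)
  tr <- generateTrial("C", 15, cfg)         # 30 positive, 150 negative
  pc <- preprocessConfig()
  rb <- rebalanceEpochs(tr, pc)
  lab <- epochLabels(rb)
  expect_equal(sum(lab == 1L), 150L)
  expect_equal(sum(lab == 0L), 150L)
  # originals first, copies appended; duplicates compare equal bit-exactly
  expect_equal(ncol(rb), 180L + 4L * 30L)
  orig <- SummarizedExperiment::assay(tr)
  dup <- SummarizedExperiment::assay(rb)
  expect_identical(dup[, seq_len(180L)], orig)
  firstPos <- which(epochLabels(tr) == 1L)[1L]
  expect_identical(dup[, 181L], orig[, firstPos])
  # factor 0 is the identity
  expect_identical(
    SummarizedExperiment::assay(rebalanceEpochs(tr, preprocessConfig(duplicationFactor = 0L))),
    orig)
  # single positive epoch, factor 4 -> 5 epochs
  one <- tr[, firstPos]
  expect_equal(ncol(rebalanceEpochs(one, pc)), 5L)
})

test_that("the pipeline runs window -> filter -> normalize -> rebalance", {
  cfg <- tinySynthConfig(seed = 9)
  tr <- generateTrial("D", 2, cfg)
  pp <- preprocessEpochs(tr, preprocessConfig(), rebalance = TRUE)
  flags <- S4Vectors::metadata(pp)$preprocessing
  expect_true(flags$windowed && flags$filtered && flags$normalized &&
                flags$rebalanced)
  # normalization is the last per-epoch transform: stats hold on the output
  e <- epochSignals(pp, 3)
  expect_lt(abs(mean(e)), 1e-9)
  expect_lt(abs(mean((e - mean(e))^2) - 1), 1e-9)
  # and filtering happened before: a raw epoch is not normalized
  raw <- epochSignals(tr, 3)
  expect_gt(abs(mean((raw - mean(raw))^2) - 1), 1e-3)
})
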