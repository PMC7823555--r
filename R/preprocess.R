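#' @include container.R
NULL

#' Configure the preprocessing chain
#'
#' @param windowStart,windowEnd epoch window in seconds post flash (default
#'   0 to 0.670, i.e. 160 samples at 240 Hz).
#' @param fs sampling rate in Hz (default 240).
#' @param bandLow,bandHigh Chebyshev type-I bandpass edges in Hz (default
#'   0.1-20).
#' @param filterOrder Chebyshev design order parameter (default 4; the
#'   bandpass transfer function has order 8).
#' @param passbandRippleDb passband ripple in dB (default 0.5).
#' @param duplicationFactor extra copies per positive epoch when rebalancing
#'   (default 4: 30 positives and 150 negatives per character become 150/150).
#' @param zeroPhase forward-backward (zero-phase) filtering instead of the
#'   default causal single pass.
#' @param perChannelNorm normalize each channel separately instead of the
#'   whole channels-by-time sample.
#' @return a [PreprocessConfig-class].
#' @export
preprocessConfig <- function(windowStart = 0, windowEnd = 0.670, fs = 240,
                             bandLow = 0.1, bandHigh = 20, filterOrder = 4L,
                             passbandRippleDb = 0.5, duplicationFactor = 4L,
                             zeroPhase = FALSE, perChannelNorm = FALSE) {
  new("PreprocessConfig", windowStart = windowStart, windowEnd = windowEnd,
      fs = fs, bandLow = bandLow, bandHigh = bandHigh,
      filterOrder = as.integer(filterOrder),
      passbandRippleDb = passbandRippleDb,
      duplicationFactor = as.integer(duplicationFactor),
      zeroPhase = zeroPhase, perChannelNorm = perChannelNorm)
}

#' Number of samples in the preprocessing window
#'
#' floor(duration * fs): 0-670 ms at 240 Hz gives 160 samples.
#'
#' @param config a [PreprocessConfig-class].
#' @export
windowSamples <- function(config)
  as.integer(floor((config@windowEnd - config@windowStart) * config@fs))

#' Cut flash-locked epochs out of a continuous recording
#'
#' Extracts, for every flash onset, the window \code{[windowStart, windowEnd)}
#' seconds post onset (0-based samples, start inclusive).
#'
#' @param recording channels x time numeric matrix.
#' @param flashOnsets 0-based onset sample indices, one per flash event.
#' @param config a [PreprocessConfig-class].
#' @param flashIndex,repetitionIndex,characterIndex,label optional per-event
#'   annotation; by default events are assumed to arrive in presentation
#'   order, 12 per repetition.
#' @param layout the [SpellerMatrix-class] for the container metadata.
#' @param targets optional per-trial attended characters.
#' @return an [EpochSet-class] of raw windowed epochs.
#' @export
extractWindow <- function(recording, flashOnsets, config = preprocessConfig(),
                          flashIndex = NULL, repetitionIndex = NULL,
                          characterIndex = NULL, label = NULL,
                          layout = spellerMatrix(), targets = NULL) {
  stopIfNot(is.matrix(recording) && is.numeric(recording),
            "invalid argument: recording must be a channels x time matrix")
  n <- length(flashOnsets)
  stopIfNot(n >= 1L, "invalid argument: no flash onsets given")
  L <- windowSamples(config)
  start <- as.integer(round(config@windowStart * config@fs))
  bad <- which(flashOnsets + start + L > ncol(recording))
  if (length(bad))
    stop("invalid argument: flash onset ", flashOnsets[bad[1L]],
         " too close to the recording end (needs ", L, " samples)",
         call. = FALSE)
  if (is.null(flashIndex)) flashIndex <- (seq_len(n) - 1L) %% 12L + 1L
  if (is.null(repetitionIndex)) repetitionIndex <- (seq_len(n) - 1L) %/% 12L + 1L
  if (is.null(characterIndex)) characterIndex <- rep(1L, n)
  if (is.null(label)) label <- rep(NA_integer_, n)
  arr <- array(0, dim = c(nrow(recording), L, n))
  for (k in seq_len(n)) {
    from <- flashOnsets[k] + start + 1L        # to 1-based column index
    arr[, , k] <- recording[, from:(from + L - 1L)]
  }
  EpochSet(arr, flashIndex = flashIndex, repetitionIndex = repetitionIndex,
           characterIndex = characterIndex, label = label, fs = config@fs,
           layout = layout, targets = targets,
           preprocessing = list(windowed = TRUE, filtered = FALSE,
                                normalized = FALSE, rebalanced = FALSE))
}

# Chebyshev type-I bandpass design for a config; returns list(b, a).
designBandpass <- function(config) {
  flt <- signal::cheby1(config@filterOrder, config@passbandRippleDb,
                        c(config@bandLow, config@bandHigh) / (config@fs / 2),
                        type = "pass")
  list(b = as.numeric(flt$b), a = as.numeric(flt$a))
}

#' Frequency response magnitude of the configured bandpass
#'
#' Evaluates |H(e^{i 2 pi f / fs})| of the designed transfer function
#' directly from its coefficients.
#'
#' @param config a [PreprocessConfig-class].
#' @param freqs frequencies in Hz.
#' @return numeric vector of gain magnitudes.
#' @export
bandpassResponse <- function(config, freqs) {
  d <- designBandpass(config)
  k <- seq_along(d$b) - 1L
  vapply(freqs, function(f) {
    z <- exp(-1i * 2 * pi * f / config@fs)
    Mod(sum(d$b * z^k) / sum(d$a * z^k))
  }, numeric(1L))
}

# Causal IIR filtering of every column of a time x series matrix with zero
# initial conditions, via the two-stage FIR + recursive form of stats::filter
# (both stages are C loops and operate column-wise).
applyIIRCols <- function(b, a, X) {
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1L, ncol(X)), X)        # zero history for the FIR
  v <- stats::filter(Xp, b / a[1L], method = "convolution", sides = 1L)
  v <- v[nb:(nrow(Xp)), , drop = FALSE]
  out <- stats::filter(v, -a[-1L] / a[1L], method = "recursive")
  matrix(as.numeric(out), nrow(X), ncol(X))
}

#' Bandpass filter epochs
#'
#' Each channel is filtered independently with the configured Chebyshev
#' type-I bandpass. The default application is a causal single pass (as a
#' real-time speller would run); set \code{zeroPhase} in the config for
#' forward-backward filtering.
#'
#' @param x a channels x time matrix or an [EpochSet-class].
#' @param config a [PreprocessConfig-class].
#' @return the filtered object, same shape/class as the input.
#' @export
bandpassFilter <- function(x, config = preprocessConfig()) {
  d <- designBandpass(config)
  if (is(x, "EpochSet")) {
    md <- metadata(x)
    arr <- epochArray(x)
    # stack time courses: all (channel, epoch) series as columns
    Xc <- matrix(aperm(arr, c(2L, 1L, 3L)), nrow = md$epochLen)
    Yc <- filterCols(d, Xc, config@zeroPhase)
    out <- aperm(array(Yc, dim = c(md$epochLen, md$nChannels, ncol(x))),
                 c(2L, 1L, 3L))
    y <- EpochSet(out, flashIndex = flashIndex(x),
                  repetitionIndex = repetitionIndex(x),
                  characterIndex = characterIndex(x), label = epochLabels(x),
                  fs = md$fs, layout = md$layout, targets = md$targets,
                  preprocessing = md$preprocessing)
    return(setProvenance(y, "filtered"))
  }
  stopIfNot(is.matrix(x), "invalid argument: x must be a matrix or EpochSet")
  assertFinite(x, "epoch")
  stopIfNot(ncol(x) > 3L * (length(d$a) - 1L),
            "invalid argument: epoch too short for the filter order")
  t(filterCols(d, t(x), config@zeroPhase))
}

filterCols <- function(d, Xc, zeroPhase) {
  assertFinite(Xc, "epoch")
  Y <- applyIIRCols(d$b, d$a, Xc)
  if (zeroPhase) {
    Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
    Y <- applyIIRCols(d$b, d$a, Y)
    Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  }
  Y
}

#' Normalize an epoch to zero mean and unit variance
#'
#' Statistics are computed over all channel-time entries of the sample
#' (population variance); with \code{perChannelNorm} each channel is
#' standardized separately.
#'
#' @param x a channels x time matrix or an [EpochSet-class] (normalized
#'   epoch-wise).
#' @param config a [PreprocessConfig-class] (only \code{perChannelNorm} is
#'   consulted).
#' @return the normalized object, same shape/class as the input.
#' @export
normalizeEpochs <- function(x, config = preprocessConfig()) {
  if (is(x, "EpochSet")) {
    md <- metadata(x)
    sig <- assay(x, "signals")
    if (config@perChannelNorm) {
      arr <- array(sig, c(md$nChannels, md$epochLen, ncol(sig)))
      for (k in seq_len(dim(arr)[3L]))
        arr[, , k] <- normalizeMatrix(arr[, , k], TRUE)
      sig <- matrix(arr, nrow(sig), ncol(sig))
    } else {
      mu <- colMeans(sig)
      sdv <- sqrt(colMeans(sig^2) - mu^2)
      if (any(sdv < 1e-12))
        stop("degenerate input: epoch ", which(sdv < 1e-12)[1L],
             " has zero variance", call. = FALSE)
      sig <- sweep(sweep(sig, 2L, mu, "-"), 2L, sdv, "/")
    }
    y <- EpochSet(array(sig, c(md$nChannels, md$epochLen, ncol(sig))),
                  flashIndex = flashIndex(x),
                  repetitionIndex = repetitionIndex(x),
                  characterIndex = characterIndex(x), label = epochLabels(x),
                  fs = md$fs, layout = md$layout, targets = md$targets,
                  preprocessing = md$preprocessing)
    return(setProvenance(y, "normalized"))
  }
  stopIfNot(is.matrix(x), "invalid argument: x must be a matrix or EpochSet")
  normalizeMatrix(x, config@perChannelNorm)
}

normalizeMatrix <- function(x, perChannel) {
  if (perChannel) {
    mu <- rowMeans(x)
    sdv <- sqrt(rowMeans(x^2) - mu^2)
    if (any(sdv < 1e-12))
      stop("degenerate input: zero-variance channel", call. = FALSE)
    (x - mu) / sdv
  } else {
    mu <- mean(x)
    sdv <- sqrt(mean((x - mu)^2))
    if (sdv < 1e-12)
      stop("degenerate input: zero-variance epoch", call. = FALSE)
    (x - mu) / sdv
  }
}

#' Rebalance classes by duplicating positive epochs
#'
#' Appends \code{duplicationFactor} extra bit-exact copies of every positive
#' epoch, so each positive appears 1 + factor times while negatives are
#' untouched. With the paradigm's 1:5 class ratio and the default factor 4
#' the classes become exactly balanced. Apply to training data only (after
#' any train/validation split, to avoid duplicate leakage).
#'
#' @param x an [EpochSet-class] with binary labels.
#' @param config a [PreprocessConfig-class].
#' @return the rebalanced [EpochSet-class] (originals first, copies appended).
#' @export
rebalanceEpochs <- function(x, config = preprocessConfig()) {
  lab <- epochLabels(x)
  stopIfNot(all(lab %in% c(0L, 1L)),
            "invalid argument: rebalancing needs binary labels")
  f <- config@duplicationFactor
  if (f == 0L) return(x)
  idx <- c(seq_len(ncol(x)), rep(which(lab == 1L), f))
  y <- x[, idx]
  setProvenance(y, "rebalanced")
}

#' Run the preprocessing chain on windowed epochs
#'
#' Applies the standard order — bandpass filter, then per-sample
#' normalization, then (optionally, training data only) class rebalancing —
#' to already-windowed epochs.
#'
#' @param x an [EpochSet-class] of raw windowed epochs.
#' @param config a [PreprocessConfig-class].
#' @param rebalance duplicate positive epochs after normalization (training
#'   sets only).
#' @return the preprocessed [EpochSet-class].
#' @export
preprocessEpochs <- function(x, config = preprocessConfig(),
                             rebalance = FALSE) {
  x <- bandpassFilter(x, config)
  x <- normalizeEpochs(x, config)
  if (rebalance) x <- rebalanceEpochs(x, config)
  x
}
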