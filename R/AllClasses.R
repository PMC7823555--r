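#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# Speller paradigm classes
# ---------------------------------------------------------------------------

#' The 6x6 speller character matrix
#'
#' Represents the row/column speller grid used in the oddball paradigm: 36
#' distinct characters arranged in 6 rows and 6 columns. Flash indices follow
#' the standard convention: index i in 1..6 denotes row i, and i in 7..12
#' denotes column i - 6.
#'
#' @slot layout a 6 x 6 character matrix of distinct single characters.
#' @export
setClass("SpellerMatrix", representation(layout = "matrix"))

setValidity("SpellerMatrix", function(object) {
  l <- object@layout
  if (!is.character(l) || !identical(dim(l), c(6L, 6L)))
    return("layout must be a 6 x 6 character matrix")
  if (any(nchar(l) != 1L)) return("all cells must be single characters")
  if (anyDuplicated(as.vector(l))) return("the 36 characters must be distinct")
  TRUE
})

#' Randomized flash schedule of a character trial
#'
#' One row per repetition; each row is a uniform-random permutation of the 12
#' flash indices (6 rows then 6 columns of the speller matrix).
#'
#' @slot order integer matrix, n_repetitions x 12, each row a permutation of 1:12.
#' @export
setClass("FlashSchedule", representation(order = "matrix"))

setValidity("FlashSchedule", function(object) {
  o <- object@order
  if (!is.matrix(o) || ncol(o) != 12L || nrow(o) < 1L)
    return("order must be an n_repetitions x 12 matrix")
  ok <- apply(o, 1L, function(r) identical(sort(as.integer(r)), 1:12))
  if (!all(ok)) return("every repetition must contain each flash index exactly once")
  TRUE
})

#' Accumulated per-flash-index detection scores for one character trial
#'
#' @slot y numeric length-12 vector of accumulated P300 probabilities, indexed
#'   by flash index (1..6 rows, 7..12 columns).
#' @slot nEpochsUsed integer, number of repetitions accumulated.
#' @export
setClass("ScoreTable",
         representation(y = "numeric", nEpochsUsed = "integer"))

setValidity("ScoreTable", function(object) {
  if (length(object@y) != 12L) return("y must have length 12")
  if (!all(is.finite(object@y))) return("y must be finite")
  if (any(object@y < 0)) return("y must be non-negative")
  TRUE
})

# ---------------------------------------------------------------------------
# Configuration classes
# ---------------------------------------------------------------------------

#' Synthetic oddball EEG generator configuration
#'
#' Parameters of the simulated P300 speller recordings: epoch geometry, the
#' P300-like deflection (a Gaussian bump peaking near 300 ms on target
#' epochs), its trial-to-trial latency jitter, the spatial topography over
#' channels, and the noise model (white plus pink Gaussian background and a
#' shared sinusoidal nuisance carrying no label information).
#'
#' @slot nChannels number of EEG channels (default 64).
#' @slot fs sampling rate in Hz (default 240).
#' @slot epochLen epoch length in samples (default 160, i.e. 0-670 ms at 240 Hz).
#' @slot p300Latency peak latency of the target deflection in seconds (default 0.300).
#' @slot p300Width Gaussian width (standard deviation) of the deflection in
#'   seconds (default 0.100).
#' @slot p300Amplitude peak amplitude of the deflection, signal units (default 1).
#' @slot latencyJitterSD per-epoch latency jitter standard deviation in seconds
#'   (default 0.02).
#' @slot noiseSD background noise standard deviation, signal units (default 1.5).
#' @slot pinkFraction fraction of the noise variance carried by the 1/f (pink)
#'   component, in [0, 1] (default 0.5).
#' @slot spatialProfile per-channel weight of the deflection in [0, 1]; default
#'   is a centro-parietal-like bump over a contiguous third of the channels.
#' @slot nuisanceAmplitude amplitude of the shared sinusoidal interference
#'   (default 1).
#' @slot nuisanceFreq frequency of the interference in Hz (default 10).
#' @slot seed integer master seed.
#' @export
setClass("SyntheticConfig", representation(
  nChannels = "integer", fs = "numeric", epochLen = "integer",
  p300Latency = "numeric", p300Width = "numeric", p300Amplitude = "numeric",
  latencyJitterSD = "numeric", noiseSD = "numeric", pinkFraction = "numeric",
  spatialProfile = "numeric", nuisanceAmplitude = "numeric",
  nuisanceFreq = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  if (object@fs <= 0) return("fs must be positive")
  if (object@epochLen < 1L) return("epochLen must be >= 1")
  if (object@p300Width <= 0) return("p300Width must be positive")
  if (object@noiseSD < 0) return("noiseSD must be non-negative")
  if (object@pinkFraction < 0 || object@pinkFraction > 1)
    return("pinkFraction must lie in [0, 1]")
  if (length(object@spatialProfile) != object@nChannels)
    return("spatialProfile must have one weight per channel")
  if (any(object@spatialProfile < 0) || any(object@spatialProfile > 1))
    return("spatialProfile weights must lie in [0, 1]")
  if (object@latencyJitterSD < 0) return("latencyJitterSD must be non-negative")
  TRUE
})

#' Preprocessing configuration
#'
#' The four-step preprocessing chain: window extraction (0-670 ms post flash),
#' Chebyshev type-I bandpass (0.1-20 Hz, order parameter 4, 0.5 dB passband
#' ripple), per-sample normalization to zero mean and unit variance, and
#' rebalancing of the rare target class by duplication (factor 4).
#'
#' @slot windowStart,windowEnd epoch window in seconds post flash onset;
#'   half-open, 0-based sample convention, sample count floor(duration * fs).
#' @slot fs sampling rate in Hz.
#' @slot bandLow,bandHigh bandpass edges in Hz.
#' @slot filterOrder Chebyshev design order parameter (the bandpass transfer
#'   function has twice this order).
#' @slot passbandRippleDb passband ripple in dB.
#' @slot duplicationFactor number of extra copies appended for each positive
#'   epoch during rebalancing.
#' @slot zeroPhase if TRUE filter forward-backward (zero phase); default FALSE,
#'   causal single pass as in online use.
#' @slot perChannelNorm if TRUE normalize each channel separately; default
#'   FALSE, whole channels-by-time sample.
#' @export
setClass("PreprocessConfig", representation(
  windowStart = "numeric", windowEnd = "numeric", fs = "numeric",
  bandLow = "numeric", bandHigh = "numeric", filterOrder = "integer",
  passbandRippleDb = "numeric", duplicationFactor = "integer",
  zeroPhase = "logical", perChannelNorm = "logical"))

setValidity("PreprocessConfig", function(object) {
  if (object@windowStart < 0 || object@windowStart >= object@windowEnd)
    return("window must satisfy 0 <= start < end")
  if (object@bandLow <= 0 || object@bandLow >= object@bandHigh ||
      object@bandHigh >= object@fs / 2)
    return("band must satisfy 0 < low < high < fs/2")
  if (object@filterOrder < 1L) return("filterOrder must be >= 1")
  if (object@duplicationFactor < 0L) return("duplicationFactor must be >= 0")
  TRUE
})

#' VIB network configuration
#'
#' Hyperparameters of the convolutional variational-information-bottleneck
#' classifier: a spatial convolution spanning all channels, a strided temporal
#' convolution acting as filter and sub-sampler, two fully connected heads
#' emitting the latent Gaussian mean and log standard deviation, and a
#' dropout + sigmoid detection head.
#'
#' @slot nChannels,epochLen input epoch geometry.
#' @slot nSpatialFilters number of spatial filters (default 10).
#' @slot temporalKernel,temporalStride temporal convolution kernel length and
#'   stride in samples (defaults 13/13).
#' @slot nTemporalFilters number of temporal filters (default 50).
#' @slot latentDim size J of the latent code z (default 64).
#' @slot beta non-negative weight of the KL (bottleneck) term.
#' @slot dropout drop probability p of the classifier dropout (default 0.5).
#' @slot mcSamples Monte Carlo samples per input for the loss (default 1).
#' @slot seed integer seed for parameter initialization.
#' @export
setClass("VIBConfig", representation(
  nChannels = "integer", epochLen = "integer", nSpatialFilters = "integer",
  temporalKernel = "integer", temporalStride = "integer",
  nTemporalFilters = "integer", latentDim = "integer", beta = "numeric",
  dropout = "numeric", mcSamples = "integer", seed = "integer"))

setValidity("VIBConfig", function(object) {
  if (object@beta < 0) return("beta must be non-negative")
  if (object@dropout < 0 || object@dropout >= 1)
    return("dropout must lie in [0, 1)")
  if (object@latentDim < 1L) return("latentDim must be >= 1")
  if (object@mcSamples < 1L) return("mcSamples must be >= 1")
  if (object@temporalKernel > object@epochLen)
    return("temporalKernel cannot exceed epochLen")
  if (object@temporalStride < 1L) return("temporalStride must be >= 1")
  TRUE
})

#' Training configuration
#'
#' @slot optimizer optimization method, "adam" or "sgd".
#' @slot learningRate step size (default 1e-3).
#' @slot batchSize minibatch size (default 64).
#' @slot nPasses number of passes over the training data.
#' @slot patience early-stopping patience in passes on the validation loss;
#'   Inf disables early stopping.
#' @slot seed integer seed controlling data order, latent draws and dropout
#'   masks during training.
#' @export
setClass("TrainConfig", representation(
  optimizer = "character", learningRate = "numeric", batchSize = "integer",
  nPasses = "integer", patience = "numeric", seed = "integer"))

setValidity("TrainConfig", function(object) {
  if (object@learningRate <= 0) return("learningRate must be positive")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (!object@optimizer %in% c("adam", "sgd"))
    return("optimizer must be 'adam' or 'sgd'")
  TRUE
})

# ---------------------------------------------------------------------------
# Model classes
# ---------------------------------------------------------------------------

#' Latent Gaussian parameters produced by the encoder
#'
#' @slot mu length-J mean vector.
#' @slot logScale length-J log standard deviation vector (sigma = exp(logScale)).
#' @export
setClass("EncoderOutput", representation(mu = "numeric", logScale = "numeric"))

setValidity("EncoderOutput", function(object) {
  if (length(object@mu) != length(object@logScale))
    return("mu and logScale must have equal length")
  if (!all(is.finite(object@mu)) || !all(is.finite(object@logScale)))
    return("mu and logScale must be finite")
  TRUE
})

#' One reparameterized latent sample
#'
#' z = mu + exp(logScale) * epsilon, with epsilon the standard normal draw
#' actually used, retained so the sample can be reproduced and gradients flow
#' only through mu and logScale.
#'
#' @slot z length-J latent vector.
#' @slot epsilon the standard normal draw used.
#' @export
setClass("LatentSample", representation(z = "numeric", epsilon = "numeric"))

setValidity("LatentSample", function(object) {
  if (length(object@z) != length(object@epsilon))
    return("z and epsilon must have equal length")
  TRUE
})

#' The VIB speller detection network
#'
#' Holds the network weights, its configuration and (after training) the
#' recorded loss history.
#'
#' @slot params named list of weight matrices and bias vectors.
#' @slot config the [VIBConfig-class] the parameters were built for.
#' @slot history list with per-pass training (and optionally validation) loss.
#' @export
setClass("VIBModel", representation(
  params = "list", config = "VIBConfig", history = "list"))

# ---------------------------------------------------------------------------
# Epoch container
# ---------------------------------------------------------------------------

#' Flash-locked EEG epoch container
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' column per flash-locked epoch. The single assay "signals" stores each
#' epoch's channels-by-time matrix flattened column-wise (channel fastest).
#' Per-epoch annotation lives in colData (flashIndex, repetitionIndex,
#' characterIndex, label); recording-level metadata (sampling rate, epoch
#' geometry, speller layout, per-trial target characters, preprocessing
#' provenance flags) lives in metadata().
#'
#' @export
setClass("EpochSet", contains = "SummarizedExperiment")

setValidity("EpochSet", function(object) {
  md <- S4Vectors::metadata(object)
  need <- c("nChannels", "epochLen", "fs", "layout", "preprocessing")
  if (!all(need %in% names(md)))
    return(paste("metadata must contain:", paste(need, collapse = ", ")))
  if (!"signals" %in% SummarizedExperiment::assayNames(object))
    return("assay 'signals' is required")
  if (nrow(object) != md$nChannels * md$epochLen)
    return("assay rows must equal nChannels * epochLen")
  cd <- SummarizedExperiment::colData(object)
  for (f in c("flashIndex", "repetitionIndex", "characterIndex", "label"))
    if (!f %in% names(cd)) return(paste("colData must contain", f))
  fi <- cd$flashIndex
  if (length(fi) && (any(fi < 1L) || any(fi > 12L)))
    return("flashIndex must lie in 1..12")
  lab <- cd$label
  if (length(lab) && !all(is.na(lab) | lab %in% c(0L, 1L)))
    return("label must be 0, 1 or NA")
  TRUE
})
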