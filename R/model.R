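#' @include AllClasses.R container.R
NULL

#' Configure the VIB detection network
#'
#' Architecture defaults follow the classic convolutional P300 detector the
#' network extends: a spatial convolution whose kernel spans all channels at
#' one time point (10 filters), a strided temporal convolution acting as
#' filter and sub-sampler (kernel 13, stride 13, 50 filters, tanh), a flatten
#' stage, two fully connected heads emitting the latent Gaussian mean and log
#' standard deviation (J = 64), and a dropout (p = 0.5) + sigmoid detection
#' head on the reparameterized latent sample.
#'
#' @param nChannels,epochLen input geometry (defaults 64 x 160).
#' @param nSpatialFilters,temporalKernel,temporalStride,nTemporalFilters
#'   convolutional stage sizes.
#' @param latentDim latent code size J.
#' @param beta bottleneck weight of the KL term in the loss.
#' @param dropout drop probability p of the classifier dropout.
#' @param mcSamples Monte Carlo samples per input in the loss estimate.
#' @param seed seed for parameter initialization.
#' @return a [VIBConfig-class].
#' @export
vibConfig <- function(nChannels = 64L, epochLen = 160L,
                      nSpatialFilters = 10L, temporalKernel = 13L,
                      temporalStride = 13L, nTemporalFilters = 50L,
                      latentDim = 64L, beta = 0.01, dropout = 0.5,
                      mcSamples = 1L, seed = 1L) {
  new("VIBConfig", nChannels = as.integer(nChannels),
      epochLen = as.integer(epochLen),
      nSpatialFilters = as.integer(nSpatialFilters),
      temporalKernel = as.integer(temporalKernel),
      temporalStride = as.integer(temporalStride),
      nTemporalFilters = as.integer(nTemporalFilters),
      latentDim = as.integer(latentDim), beta = beta, dropout = dropout,
      mcSamples = as.integer(mcSamples), seed = as.integer(seed))
}

# Temporal positions after the strided convolution.
nTemporalPositions <- function(cfg)
  as.integer((cfg@epochLen - cfg@temporalKernel) %/% cfg@temporalStride + 1L)

# Flattened feature length entering the fully connected heads.
flatFeatures <- function(cfg) cfg@nTemporalFilters * nTemporalPositions(cfg)

#' Initialize a VIB model
#'
#' Weights are drawn from zero-mean Gaussians scaled by 1/sqrt(fan-in); the
#' log-scale head bias starts at -2 so the latent noise begins small relative
#' to the mean pathway.
#'
#' @param config a [VIBConfig-class].
#' @return a [VIBModel-class].
#' @export
initVIBModel <- function(config) {
  validObject(config)
  S <- config@nSpatialFilters; C <- config@nChannels
  K <- config@nTemporalFilters; Tk <- config@temporalKernel
  J <- config@latentDim; Fl <- flatFeatures(config)
  gauss <- function(nr, nc) matrix(rnorm(nr * nc, 0, 1 / sqrt(nc)), nr, nc)
  params <- withSeed(config@seed, list(
    W1 = gauss(S, C),            b1 = numeric(S),
    W2 = gauss(K, S * Tk),       b2 = numeric(K),
    Wmu = gauss(J, Fl),          bmu = numeric(J),
    Wsig = gauss(J, Fl),         bsig = rep(-2, J),
    wout = rnorm(J, 0, 1 / sqrt(J)), bout = 0))
  new("VIBModel", params = params, config = config, history = list())
}

setMethod("modelConfig", "VIBModel", function(object) object@config)
setMethod("modelParams", "VIBModel", function(object) object@params)
setMethod("lossHistory", "VIBModel", function(object) object@history)

setMethod("show", "VIBModel", function(object) {
  cfg <- object@config
  cat("VIBModel:", cfg@nChannels, "x", cfg@epochLen, "input ->",
      cfg@nSpatialFilters, "spatial,", cfg@nTemporalFilters,
      "temporal filters -> J =", cfg@latentDim, "\n")
  cat("  beta =", cfg@beta, " dropout p =", cfg@dropout, "\n")
  if (length(object@history$train))
    cat("  trained:", length(object@history$train), "pass(es), final loss",
        signif(utils::tail(object@history$train, 1L), 4L), "\n")
})

# Coerce an input batch (matrix, 3-D array or EpochSet) to C x T x N.
asEpochBatch <- function(x, cfg) {
  if (is(x, "EpochSet")) x <- epochArray(x)
  if (is.matrix(x)) x <- array(x, dim = c(nrow(x), ncol(x), 1L))
  d <- dim(x)
  if (length(d) != 3L || d[1L] != cfg@nChannels || d[2L] != cfg@epochLen)
    stop("invalid argument: expected epochs of shape ", cfg@nChannels, " x ",
         cfg@epochLen, ", got ", paste(d, collapse = " x "), call. = FALSE)
  x
}

# Deterministic encoder pass for a batch. Returns all intermediates needed
# by backprop. Layer order: spatial conv (linear) -> strided temporal conv
# (tanh) -> flatten -> two linear heads (mu, sigma-hat).
encoderForward <- function(params, cfg, X) {
  d <- dim(X); N <- d[3L]
  Tlen <- cfg@epochLen; S <- cfg@nSpatialFilters
  Tk <- cfg@temporalKernel; P <- nTemporalPositions(cfg)
  Xmat <- matrix(X, nrow = d[1L])                       # C x (T*N)
  A1 <- params$W1 %*% Xmat + params$b1                  # S x (T*N)
  # gather the strided windows: columns ordered p fastest within epoch
  base <- outer(seq_len(Tk), (seq_len(P) - 1L) * cfg@temporalStride, "+")
  colsel <- as.integer(outer(as.vector(base), (seq_len(N) - 1L) * Tlen, "+"))
  U <- matrix(A1[, colsel], nrow = S * Tk)              # (S*Tk) x (P*N)
  Z2 <- params$W2 %*% U + params$b2                     # K x (P*N)
  A2 <- tanh(Z2)
  H <- matrix(A2, nrow = cfg@nTemporalFilters * P)      # F x N
  Mu <- params$Wmu %*% H + params$bmu                   # J x N
  Sig <- params$Wsig %*% H + params$bsig                # J x N (sigma-hat)
  list(Xmat = Xmat, A1 = A1, U = U, A2 = A2, H = H, Mu = Mu, Sig = Sig,
       colsel = colsel, N = N, P = P)
}

#' Encode an epoch into latent Gaussian parameters
#'
#' @param object a [VIBModel-class].
#' @param x one preprocessed epoch (channels x time matrix) or an
#'   [EpochSet-class]/array batch; for batches a J x N matrix is returned in
#'   each slot.
#' @return an [EncoderOutput-class] for a single epoch, otherwise a list with
#'   elements \code{mu} and \code{logScale}.
#' @export
setMethod("encode", "VIBModel", function(object, x, ...) {
  X <- asEpochBatch(x, object@config)
  fw <- encoderForward(object@params, object@config, X)
  if (dim(X)[3L] == 1L)
    new("EncoderOutput", mu = as.numeric(fw$Mu), logScale = as.numeric(fw$Sig))
  else list(mu = fw$Mu, logScale = fw$Sig)
})

#' Reparameterize a latent draw
#'
#' z = mu + exp(logScale) * epsilon. The standard normal draw epsilon is
#' independent of the network parameters, so gradients flow only through mu
#' and logScale.
#'
#' @param out an [EncoderOutput-class].
#' @param epsilon a standard normal vector of length J; drawn internally when
#'   omitted.
#' @return a [LatentSample-class].
#' @export
reparameterize <- function(out, epsilon = NULL) {
  J <- length(out@mu)
  if (is.null(epsilon)) epsilon <- rnorm(J)
  if (length(epsilon) != J)
    stop("invalid argument: epsilon length ", length(epsilon),
         " does not match J = ", J, call. = FALSE)
  new("LatentSample", z = out@mu + exp(out@logScale) * epsilon,
      epsilon = epsilon)
}

#' Classify a latent sample
#'
#' The detection head: in training mode an elementwise Bernoulli keep mask
#' (keep probability 1 - p) is applied to z before the affine map and
#' sigmoid; in inference mode no mask is applied and the weights are rescaled
#' by 1 - p (the standard dropout expectation convention).
#'
#' @param model a [VIBModel-class].
#' @param z a [LatentSample-class] or numeric latent vector.
#' @param training logical; apply dropout sampling.
#' @param mask optional 0/1 keep mask (training mode), for reproducibility.
#' @return the detection probability in (0, 1).
#' @export
classifyLatent <- function(model, z, training = FALSE, mask = NULL) {
  if (is(z, "LatentSample")) z <- z@z
  assertFinite(z, "z")
  p <- model@config@dropout
  w <- model@params$wout
  if (training) {
    if (is.null(mask)) mask <- as.numeric(runif(length(z)) >= p)
    pre <- sum(w * (mask * z)) + model@params$bout
  } else {
    pre <- (1 - p) * sum(w * z) + model@params$bout
  }
  sigmoid(pre)
}

#' KL divergence of the encoder posterior from the standard normal prior
#'
#' The closed form for diagonal Gaussians against N(0, I):
#' -(1/2) sum_j [1 + log sigma_j^2 - mu_j^2 - sigma_j^2], sigma_j =
#' exp(logScale_j). Always non-negative; zero iff mu = 0 and sigma = 1.
#'
#' @param object an [EncoderOutput-class].
#' @return a non-negative scalar.
#' @export
setMethod("klTerm", "EncoderOutput", function(object) {
  assertFinite(c(object@mu, object@logScale), "encoder output")
  klFromMats(object@mu, object@logScale)
})

klFromMats <- function(Mu, Sig) {
  # columns = samples; returns per-sample KL (scalar for vectors)
  if (is.matrix(Mu)) 0.5 * colSums(Mu^2 + exp(2 * Sig) - 1 - 2 * Sig)
  else 0.5 * sum(Mu^2 + exp(2 * Sig) - 1 - 2 * Sig)
}

# Full stochastic forward pass for a batch; eps and mask may be supplied
# frozen (J x N*mc) for gradient checks. Returns intermediates for backprop.
vibForward <- function(params, cfg, X, training = TRUE, eps = NULL,
                       mask = NULL) {
  fw <- encoderForward(params, cfg, X)
  N <- fw$N; J <- cfg@latentDim; mc <- cfg@mcSamples
  rep_idx <- rep(seq_len(N), each = mc)
  Mu_r <- fw$Mu[, rep_idx, drop = FALSE]
  Sig_r <- fw$Sig[, rep_idx, drop = FALSE]
  if (is.null(eps)) eps <- matrix(rnorm(J * N * mc), J)
  Z <- Mu_r + exp(Sig_r) * eps
  if (training) {
    if (is.null(mask))
      mask <- matrix(as.numeric(runif(J * N * mc) >= cfg@dropout), J)
    Zc <- mask * Z
    pre <- as.numeric(crossprod(params$wout, Zc)) + params$bout
  } else {
    mask <- NULL
    pre <- (1 - cfg@dropout) * as.numeric(crossprod(params$wout, Z)) +
      params$bout
  }
  c(fw, list(eps = eps, mask = mask, Z = Z, rep_idx = rep_idx,
             yhat = sigmoid(pre), training = training))
}

# Numerically safe binary cross-entropy.
bce <- function(yhat, y) {
  eps <- 1e-12
  -(y * log(pmax(yhat, eps)) + (1 - y) * log(pmax(1 - yhat, eps)))
}

#' The VIB training loss on a batch
#'
#' Mean over the batch of the Monte Carlo binary cross-entropy of the sampled
#' stochastic forward pass against the labels, plus beta times the mean
#' closed-form KL of the encoder posterior from the standard normal prior.
#'
#' @param model a [VIBModel-class].
#' @param x batch of preprocessed epochs ([EpochSet-class], array or single
#'   matrix).
#' @param labels binary labels, one per epoch (taken from the container when
#'   omitted).
#' @param eps,mask optional frozen latent draws / dropout keep masks
#'   (J x N*mcSamples) for reproducible evaluation.
#' @param training logical; stochastic (dropout-sampling) pass, the default.
#' @return a finite scalar.
#' @export
vibLoss <- function(model, x, labels = NULL, eps = NULL, mask = NULL,
                    training = TRUE) {
  cfg <- model@config
  if (is.null(labels) && is(x, "EpochSet")) labels <- epochLabels(x)
  X <- asEpochBatch(x, cfg)
  N <- dim(X)[3L]
  stopIfNot(N >= 1L, "invalid argument: empty batch")
  stopIfNot(length(labels) == N && all(labels %in% c(0, 1)),
            "invalid argument: labels must be binary, one per epoch")
  fw <- vibForward(model@params, cfg, X, training = training, eps = eps,
                   mask = mask)
  ce <- mean(bce(fw$yhat, labels[fw$rep_idx]))
  kl <- mean(klFromMats(fw$Mu, fw$Sig))
  loss <- ce + cfg@beta * kl
  if (!is.finite(loss)) stop("training failure: non-finite loss", call. = FALSE)
  loss
}

#' Loss and analytic gradients on a batch
#'
#' Backpropagates the VIB loss through the dropout head, the
#' reparameterization, both fully connected heads, the tanh temporal
#' convolution and the spatial convolution. With frozen \code{eps} and
#' \code{mask} the returned gradients are exact derivatives of [vibLoss()]
#' evaluated with the same draws.
#'
#' @inheritParams vibLoss
#' @return list with \code{loss}, \code{grads} (named like the parameter
#'   list), and the per-sample mean \code{kl}.
#' @export
vibGradients <- function(model, x, labels = NULL, eps = NULL, mask = NULL) {
  cfg <- model@config
  params <- model@params
  if (is.null(labels) && is(x, "EpochSet")) labels <- epochLabels(x)
  X <- asEpochBatch(x, cfg)
  N <- dim(X)[3L]
  stopIfNot(N >= 1L, "invalid argument: empty batch")
  stopIfNot(length(labels) == N && all(labels %in% c(0, 1)),
            "invalid argument: labels must be binary, one per epoch")
  fw <- vibForward(params, cfg, X, training = TRUE, eps = eps, mask = mask)
  mc <- cfg@mcSamples
  yrep <- labels[fw$rep_idx]
  ce <- mean(bce(fw$yhat, yrep))
  klPer <- klFromMats(fw$Mu, fw$Sig)
  loss <- ce + cfg@beta * mean(klPer)
  if (!is.finite(loss)) stop("training failure: non-finite loss", call. = FALSE)

  # ---- head ----
  dpre <- (fw$yhat - yrep) / (N * mc)                 # d(mean BCE)/d(pre)
  Zc <- fw$mask * fw$Z
  g_wout <- as.numeric(Zc %*% dpre)
  g_bout <- sum(dpre)
  dZ <- (params$wout %o% dpre) * fw$mask              # J x (N*mc)
  # ---- reparameterization ----
  Sig_r <- fw$Sig[, fw$rep_idx, drop = FALSE]
  dMu_mc <- dZ
  dSig_mc <- dZ * exp(Sig_r) * fw$eps
  collapse <- function(M) {
    if (mc == 1L) M
    else M %*% matrix(as.numeric(outer(seq_len(N * mc),
                                       seq_len(N),
                                       function(i, n) (i - 1L) %/% mc + 1L == n)),
                      N * mc, N)
  }
  dMu <- collapse(dMu_mc)
  dSig <- collapse(dSig_mc)
  # ---- KL term: d/dmu = mu, d/dsigma-hat = exp(2 sigma-hat) - 1 ----
  dMu <- dMu + (cfg@beta / N) * fw$Mu
  dSig <- dSig + (cfg@beta / N) * (exp(2 * fw$Sig) - 1)
  # ---- heads ----
  g_Wmu <- dMu %*% t(fw$H); g_bmu <- rowSums(dMu)
  g_Wsig <- dSig %*% t(fw$H); g_bsig <- rowSums(dSig)
  dH <- crossprod(params$Wmu, dMu) + crossprod(params$Wsig, dSig)  # F x N
  # ---- temporal conv (tanh) ----
  K <- cfg@nTemporalFilters; P <- fw$P
  dA2 <- matrix(dH, nrow = K)                          # K x (P*N)
  dZ2 <- dA2 * (1 - fw$A2^2)
  g_W2 <- dZ2 %*% t(fw$U); g_b2 <- rowSums(dZ2)
  dU <- crossprod(params$W2, dZ2)                      # (S*Tk) x (P*N)
  # ---- scatter the strided windows back onto the spatial maps ----
  S <- cfg@nSpatialFilters; Tk <- cfg@temporalKernel
  Tlen <- cfg@epochLen
  dA1 <- matrix(0, S, Tlen * N)
  base <- outer(seq_len(Tk), (seq_len(P) - 1L) * cfg@temporalStride, "+")
  for (p in seq_len(P)) {
    cols <- as.integer(outer(base[, p], (seq_len(N) - 1L) * Tlen, "+"))
    part <- dU[, seq(p, P * N, by = P), drop = FALSE]  # (S*Tk) x N
    dA1[, cols] <- dA1[, cols] + matrix(part, nrow = S)
  }
  g_W1 <- dA1 %*% t(fw$Xmat); g_b1 <- rowSums(dA1)
  list(loss = loss, kl = mean(klPer),
       grads = list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2,
                    Wmu = g_Wmu, bmu = g_bmu, Wsig = g_Wsig, bsig = g_bsig,
                    wout = g_wout, bout = g_bout))
}

#' Deterministic detection probabilities
#'
#' Inference rule: the latent is set to its posterior mean (epsilon = 0),
#' dropout is off and the head weights are rescaled by the keep probability.
#' Repeated calls are identical.
#'
#' @param object a [VIBModel-class].
#' @param x epochs ([EpochSet-class], channels x time x N array or a single
#'   matrix).
#' @return numeric vector of detection probabilities in (0, 1).
#' @export
setMethod("predictProb", "VIBModel", function(object, x, ...) {
  cfg <- object@config
  X <- asEpochBatch(x, cfg)
  fw <- encoderForward(object@params, cfg, X)
  pre <- (1 - cfg@dropout) *
    as.numeric(crossprod(object@params$wout, fw$Mu)) + object@params$bout
  as.numeric(sigmoid(pre))
})

#' Save / load a model checkpoint
#'
#' A single file holding the weights with the configuration embedded; loading
#' validates that every weight matrix matches the shapes the configuration
#' implies.
#'
#' @param model a [VIBModel-class].
#' @param path checkpoint file path.
#' @return \code{loadModel} returns the restored [VIBModel-class].
#' @export
saveModel <- function(model, path) {
  stopIfNot(is(model, "VIBModel"), "invalid argument: model must be a VIBModel")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("not found: ", path, call. = FALSE)
  m <- tryCatch(readRDS(path),
                error = function(e) stop("format error reading '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  if (!is(m, "VIBModel"))
    stop("format error: '", path, "' is not a VIBModel checkpoint",
         call. = FALSE)
  ref <- initVIBModel(m@config)
  for (nm in names(ref@params)) {
    want <- dim(ref@params[[nm]]); got <- dim(m@params[[nm]])
    if (!identical(want, got) ||
        length(ref@params[[nm]]) != length(m@params[[nm]]))
      stop("format error: checkpoint weight '", nm,
           "' does not match the embedded configuration", call. = FALSE)
  }
  m
}
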