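#' @include model.R preprocess.R
NULL

#' Configure training
#'
#' @param optimizer "adam" (default; the adaptive-moment stochastic gradient
#'   variant) or plain "sgd".
#' @param learningRate step size (default 1e-3).
#' @param batchSize minibatch size (default 64).
#' @param nPasses passes over the training data (default 10).
#' @param patience early-stopping patience in passes on the validation loss;
#'   Inf (default) disables early stopping.
#' @param seed seed controlling data order, latent draws and dropout masks.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(optimizer = "adam", learningRate = 1e-3,
                        batchSize = 64L, nPasses = 10L, patience = Inf,
                        seed = 1L) {
  new("TrainConfig", optimizer = optimizer, learningRate = learningRate,
      batchSize = as.integer(batchSize), nPasses = as.integer(nPasses),
      patience = as.numeric(patience), seed = as.integer(seed))
}

# One Adam / SGD update; returns list(params, state).
optimStep <- function(params, grads, state, tc, step) {
  lr <- tc@learningRate
  if (tc@optimizer == "sgd") {
    for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(params = params, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; epsl <- 1e-8
  for (nm in names(params)) {
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - b1^step)
    vhat <- state$v[[nm]] / (1 - b2^step)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + epsl)
  }
  list(params = params, state = state)
}

#' Train a VIB model
#'
#' Minimizes the VIB loss (Monte Carlo cross-entropy plus beta times the
#' Gaussian KL) by stochastic gradient steps over shuffled minibatches. All
#' randomness — data order, latent draws, dropout masks — runs under the
#' training seed, and the initialization under the model seed, so identical
#' configurations reproduce bit-identical loss histories.
#'
#' @param epochs a preprocessed, labeled (and typically rebalanced)
#'   [EpochSet-class].
#' @param config a [VIBConfig-class].
#' @param train a [TrainConfig-class].
#' @param validation optional labeled [EpochSet-class] scored (with a
#'   deterministic pass) after every training pass; required for early
#'   stopping.
#' @return a trained [VIBModel-class]; \code{lossHistory(model)$train} holds
#'   the mean minibatch loss per pass.
#' @export
trainVIB <- function(epochs, config = vibConfig(), train = trainConfig(),
                     validation = NULL) {
  labels <- epochLabels(epochs)
  stopIfNot(ncol(epochs) >= 1L && all(labels %in% c(0L, 1L)),
            "invalid argument: training needs a nonempty labeled dataset")
  X <- epochArray(epochs)
  model <- initVIBModel(config)
  params <- model@params
  state <- list(m = lapply(params, function(p) p * 0),
                v = lapply(params, function(p) p * 0))
  n <- dim(X)[3L]
  histTrain <- histVal <- numeric(0)
  bestVal <- Inf; bestParams <- params; badPasses <- 0
  step <- 0L
  withSeed(train@seed, {
    for (pass in seq_len(train@nPasses)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = train@batchSize)
      passLoss <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        idx <- ord[starts[bi]:min(starts[bi] + train@batchSize - 1L, n)]
        model@params <- params
        g <- tryCatch(
          vibGradients(model, X[, , idx, drop = FALSE], labels[idx]),
          error = function(e)
            stop("training failure at pass ", pass, ", step ", step + 1L,
                 ": ", conditionMessage(e), call. = FALSE))
        step <- step + 1L
        upd <- optimStep(params, g$grads, state, train, step)
        params <- upd$params; state <- upd$state
        passLoss[bi] <- g$loss
      }
      histTrain <- c(histTrain, mean(passLoss))
      if (!is.null(validation)) {
        model@params <- params
        vl <- vibLoss(model, validation, training = FALSE)
        histVal <- c(histVal, vl)
        if (vl < bestVal - 1e-9) {
          bestVal <- vl; bestParams <- params; badPasses <- 0
        } else {
          badPasses <- badPasses + 1
          if (badPasses > train@patience) break
        }
      }
    }
  })
  if (!is.null(validation) && is.finite(train@patience)) params <- bestParams
  model@params <- params
  model@history <- list(train = histTrain,
                        validation = if (length(histVal)) histVal else NULL)
  model
}

#' Character recognition rate versus repetition count
#'
#' For each requested repetition count k, every character trial is decoded
#' from its first k repetitions: deterministic detection probabilities are
#' accumulated per flash index and the row/column argmax picks the character.
#' The rate is 100 * correct / trials.
#'
#' @param model a trained [VIBModel-class].
#' @param trials a preprocessed (never rebalanced) [EpochSet-class] whose
#'   metadata carries the per-trial target characters.
#' @param repetitionCounts repetition counts to evaluate (default 1, 5, 10, 15).
#' @return a data.frame with columns repetitions, nCorrect, nTrials, accuracy
#'   (percent).
#' @export
evaluateCharacterAccuracy <- function(model, trials,
                                      repetitionCounts = c(1L, 5L, 10L, 15L)) {
  targets <- targetChars(trials)
  stopIfNot(!is.null(targets),
            "invalid argument: trials must carry target characters")
  maxRep <- max(repetitionIndex(trials))
  if (any(repetitionCounts > maxRep))
    stop("invalid argument: requested ", max(repetitionCounts),
         " repetitions but trials carry only ", maxRep, call. = FALSE)
  probs <- predictProb(model, trials)
  ci <- characterIndex(trials); fi <- flashIndex(trials)
  ri <- repetitionIndex(trials)
  layout <- spellerLayout(trials)
  ids <- sort(unique(ci))
  stopIfNot(length(targets) == length(ids),
            "invalid argument: one target per character trial required")
  res <- lapply(repetitionCounts, function(k) {
    correct <- 0L
    for (t in seq_along(ids)) {
      sel <- ci == ids[t]
      st <- accumulateScores(probs[sel], fi[sel], k, ri[sel])
      if (decodeCharacter(st, layout) == targets[t]) correct <- correct + 1L
    }
    data.frame(repetitions = k, nCorrect = correct, nTrials = length(ids),
               accuracy = 100 * correct / length(ids))
  })
  do.call(rbind, res)
}

#' Sweep the bottleneck weight beta
#'
#' Trains one model per (beta, replicate) on identical data — only the beta
#' and the derived seed differ — and evaluates the character recognition rate
#' at each repetition count, together with the mean per-sample KL of the
#' encoder posterior on the evaluation set (the information actually flowing
#' through the bottleneck).
#'
#' @param betas numeric vector of at least two bottleneck weights; the default
#'   grid spans 1e-4 to 100.
#' @param trainEpochs preprocessed, rebalanced training [EpochSet-class].
#' @param testTrials preprocessed evaluation [EpochSet-class] with targets.
#' @param config a [VIBConfig-class] (its beta is overridden per run).
#' @param train a [TrainConfig-class] (its seed seeds each run via a derived
#'   per-replicate stream).
#' @param repetitionCounts repetition counts to evaluate.
#' @param nReplicates random-seed replicates per beta.
#' @return a data.frame with one row per (beta, replicate, repetition count):
#'   columns beta, replicate, repetitions, accuracy, klPerSample.
#' @export
betaSweep <- function(betas = 10^seq(-4, 2), trainEpochs, testTrials,
                      config = vibConfig(), train = trainConfig(),
                      repetitionCounts = c(1L, 5L, 10L, 15L),
                      nReplicates = 1L) {
  stopIfNot(length(betas) >= 2L, "invalid argument: need at least two betas")
  rows <- list()
  for (bi in seq_along(betas)) {
    for (rep in seq_len(nReplicates)) {
      cfg <- config; cfg@beta <- betas[bi]
      tc <- train; tc@seed <- deriveSeed(train@seed, rep)
      model <- tryCatch(
        trainVIB(trainEpochs, cfg, tc),
        error = function(e) stop("beta sweep failed at beta = ", betas[bi],
                                 ": ", conditionMessage(e), call. = FALSE))
      acc <- evaluateCharacterAccuracy(model, testTrials, repetitionCounts)
      enc <- encode(model, testTrials)
      klps <- mean(klFromMats(enc$mu, enc$logScale))
      rows[[length(rows) + 1L]] <-
        data.frame(beta = betas[bi], replicate = rep,
                   repetitions = acc$repetitions, accuracy = acc$accuracy,
                   klPerSample = klps)
    }
  }
  do.call(rbind, rows)
}
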