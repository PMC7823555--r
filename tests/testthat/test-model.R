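test_that("the encoder emits length-J mu and log-scale heads", {
  cfg <- vibConfig()                 # full-size default geometry
  m <- initVIBModel(cfg)
  x <- matrix(rnorm(64 * 160), 64)
  out <- encode(m, x)
  expect_s4_class(out, "EncoderOutput")
  expect_length(out@mu, 64L)
  expect_length(out@logScale, 64L)
  # convolution arithmetic: 160 samples, kernel 13, stride 13 -> 12 positions
  expect_equal(ncol(modelParams(m)$Wmu), 50L * 12L)
  # zero network maps everything to the origin
  z <- m
  z@params <- lapply(z@params, function(p) p * 0)
  out0 <- encode(z, x)
  expect_equal(out0@mu, rep(0, 64))
  expect_equal(out0@logScale, rep(0, 64))
  expect_error(encode(m, matrix(0, 8, 160)), "expected epochs of shape")
})

test_that("reparameterization is z = mu + exp(logScale) * eps", {
  out <- new("EncoderOutput", mu = c(1, -2, 0.5), logScale = c(0, 0.3, -1))
  s0 <- reparameterize(out, c(0, 0, 0))
  expect_equal(s0@z, out@mu)
  sid <- reparameterize(new("EncoderOutput", mu = rep(0, 3),
                            logScale = rep(0, 3)), c(0.4, -1, 2))
  expect_equal(sid@z, c(0.4, -1, 2))
  expect_error(reparameterize(out, c(1, 2)), "does not match J")
  # moment recovery over 20 random parameter pairs
  set.seed(71)
  for (i in 1:20) {
    J <- sample(2:4, 1)
    mu <- rnorm(J); ls <- runif(J, -1, 0.5)
    o <- new("EncoderOutput", mu = mu, logScale = ls)
    n <- 10000L
    zs <- vapply(seq_len(n), function(k) reparameterize(o)@z, numeric(J))
    zs <- matrix(zs, nrow = J)
    sdv <- exp(ls)
    expect_true(all(abs(rowMeans(zs) - mu) < 4 * sdv / sqrt(n)))
    expect_true(all(abs(apply(zs, 1, sd) - sdv) < 4 * sdv / sqrt(2 * n)))
  }
})

test_that("the dropout + sigmoid head behaves at its fixed points", {
  m <- initVIBModel(tinyVibConfig())
  expect_equal(classifyLatent(m, rep(0, 4)), 0.5)    # z = 0, b = 0
  expect_equal(classifyLatent(m, rnorm(4), training = TRUE,
                              mask = rep(0, 4)), 0.5)  # everything dropped
  set.seed(72)
  for (i in 1:1000) {
    p <- classifyLatent(m, rnorm(4, sd = 10), training = (i %% 2 == 0))
    expect_true(p > 0 && p < 1)
  }
})

test_that("the closed-form KL matches numerical quadrature", {
  # exact zeros and the J = 1 textbook value
  expect_equal(klTerm(new("EncoderOutput", mu = rep(0, 5),
                          logScale = rep(0, 5))), 0)
  expect_equal(klTerm(new("EncoderOutput", mu = 1, logScale = 0)), 0.5)
  set.seed(73)
  for (i in 1:100) {
    J <- sample(1:4, 1)
    mu <- rnorm(J, sd = 1.5); ls <- runif(J, -1.5, 1)
    kl <- klTerm(new("EncoderOutput", mu = mu, logScale = ls))
    expect_gte(kl, 0)
    expect_equal(kl, klQuadrature(mu, ls), tolerance = 1e-6)
  }
  # zero exactly iff mu = 0 and sigma = 1, checked on a grid
  for (mu in c(-1, -0.1, 0, 0.1, 1)) for (ls in c(-0.5, -0.01, 0, 0.01, 0.5)) {
    kl <- klTerm(new("EncoderOutput", mu = mu, logScale = ls))
    if (mu == 0 && ls == 0) expect_equal(kl, 0)
    else expect_gt(kl, 0)
  }
})

test_that("the loss reduces to cross-entropy at beta 0 and adds the KL", {
  cfg <- tinyVibConfig(beta = 0)
  m <- initVIBModel(cfg)
  set.seed(74)
  X <- array(rnorm(4 * 32 * 6), c(4, 32, 6))
  y <- c(1, 0, 0, 1, 1, 0)
  eps <- matrix(rnorm(4 * 6), 4)
  mask <- matrix(as.numeric(runif(4 * 6) >= 0.5), 4)
  loss0 <- vibLoss(m, X, y, eps = eps, mask = mask)
  # manual cross-entropy of the same frozen forward pass
  manual <- mean(vapply(1:6, function(n) {
    out <- encode(m, X[, , n])
    z <- out@mu + exp(out@logScale) * eps[, n]
    p <- classifyLatent(m, z, training = TRUE, mask = mask[, n])
    -(y[n] * log(p) + (1 - y[n]) * log(1 - p))
  }, numeric(1)))
  expect_equal(loss0, manual, tolerance = 1e-12)
  # beta scales the mean KL term linearly
  cfgB <- tinyVibConfig(beta = 0.7)
  mB <- m; mB@config <- cfgB
  lossB <- vibLoss(mB, X, y, eps = eps, mask = mask)
  klMean <- mean(vapply(1:6, function(n) klTerm(encode(m, X[, , n])),
                        numeric(1)))
  expect_equal(lossB, loss0 + 0.7 * klMean, tolerance = 1e-12)
  # a perfect classifier at beta 0 has (near) zero loss
  perf <- m
  perf@params$wout <- 0 * perf@params$wout
  perf@params$bout <- 30
  expect_lt(vibLoss(perf, X, rep(1, 6), eps = eps, mask = mask), 1e-10)
  expect_error(vibLoss(m, X, y[1:3]), "labels")
})

test_that("the Monte Carlo loss agrees with quadrature on a frozen net", {
  # dropout off: the inner integral over z of -log q(y|z) is a Gaussian
  # expectation; since the pre-activation is a linear functional of z it
  # reduces exactly to a 1-D Gaussian quadrature — the independent oracle
  cfg <- tinyVibConfig(beta = 0, dropout = 0, seed = 5)
  m <- initVIBModel(cfg)
  set.seed(75)
  x <- matrix(rnorm(4 * 32), 4)
  out <- encode(m, x)
  w <- modelParams(m)$wout; b <- modelParams(m)$bout
  # analytic reduction: pre = w . z + b with z ~ N(mu, diag(sigma^2)) is a
  # 1-D Gaussian; quadrature over that single dimension is exact
  mpre <- sum(w * out@mu) + b
  spre <- sqrt(sum((w * exp(out@logScale))^2))
  quad <- stats::integrate(function(u)
    stats::dnorm(u, mpre, spre) * (-log(1 / (1 + exp(-u)))),
    mpre - 10 * spre, mpre + 10 * spre, rel.tol = 1e-10)$value
  # Monte Carlo with 10^4 frozen draws through the package forward pass
  nmc <- 10000L
  eps <- matrix(rnorm(4 * nmc), 4)
  zs <- out@mu + exp(out@logScale) * eps
  ps <- vapply(seq_len(nmc), function(k)
    classifyLatent(m, zs[, k], training = TRUE, mask = rep(1, 4)),
    numeric(1))
  draws <- -log(ps)
  mcfg <- m@config; mcfg@mcSamples <- nmc
  mMC <- m; mMC@config <- mcfg
  lossMC <- vibLoss(mMC, x, 1, eps = eps,
                    mask = matrix(1, 4, nmc))
  expect_equal(lossMC, mean(draws), tolerance = 1e-10)
  se <- sd(draws) / sqrt(nmc)
  expect_lt(abs(lossMC - quad), 4 * se)
})

test_that("analytic gradients match finite differences on a tiny network", {
  cfg <- vibConfig(nChannels = 4L, epochLen = 16L, nSpatialFilters = 2L,
                   temporalKernel = 5L, temporalStride = 3L,
                   nTemporalFilters = 3L, latentDim = 2L, beta = 0.05,
                   dropout = 0.5, mcSamples = 2L, seed = 9L)
  m <- initVIBModel(cfg)
  set.seed(76)
  N <- 5L
  X <- array(rnorm(4 * 16 * N), c(4, 16, N))
  y <- c(1, 0, 1, 0, 0)
  eps <- matrix(rnorm(2 * N * 2), 2)
  mask <- matrix(as.numeric(runif(2 * N * 2) >= 0.5), 2)
  g <- vibGradients(m, X, y, eps = eps, mask = mask)
  h <- 1e-6
  for (nm in names(m@params)) {
    p <- m@params[[nm]]
    for (i in seq_along(p)) {
      mp <- m; mp@params[[nm]][i] <- p[i] + h
      mm <- m; mm@params[[nm]][i] <- p[i] - h
      fd <- (vibLoss(mp, X, y, eps = eps, mask = mask) -
               vibLoss(mm, X, y, eps = eps, mask = mask)) / (2 * h)
      an <- g$grads[[nm]][i]
      if (abs(fd) > 1e-10 || abs(an) > 1e-10)
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
    }
  }
})

test_that("the loss is non-decreasing in beta on a frozen network", {
  cfg <- tinyVibConfig(seed = 3)
  m <- initVIBModel(cfg)
  set.seed(77)
  X <- array(rnorm(4 * 32 * 8), c(4, 32, 8))
  y <- rep(c(1, 0), 4)
  eps <- matrix(rnorm(4 * 8), 4)
  mask <- matrix(as.numeric(runif(4 * 8) >= 0.5), 4)
  losses <- vapply(c(0, 0.01, 0.1, 1, 10, 100), function(b) {
    mb <- m; mb@config@beta <- b
    vibLoss(mb, X, y, eps = eps, mask = mask)
  }, numeric(1))
  expect_true(all(diff(losses) >= 0))
})

test_that("deterministic prediction is reproducible and well-ranged", {
  cfg <- tinyVibConfig(seed = 4)
  m <- initVIBModel(cfg)
  X <- array(rnorm(4 * 32 * 10), c(4, 32, 10))
  p1 <- predictProb(m, X); p2 <- predictProb(m, X)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  # zero-weight network is maximally uncertain
  z <- m; z@params <- lapply(z@params, function(p) p * 0)
  expect_equal(predictProb(z, X), rep(0.5, 10))
})

test_that("checkpoints round-trip and validate shapes on load", {
  m <- initVIBModel(tinyVibConfig(seed = 8))
  f <- tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_identical(modelParams(m2), modelParams(m))
  expect_identical(m2@config, m@config)
  # corrupt a weight shape: loading must fail with a format error
  bad <- m
  bad@params$Wmu <- matrix(0, 2, 2)
  saveRDS(bad, f)
  expect_error(loadModel(f), "does not match the embedded configuration")
  expect_error(loadModel(tempfile()), "not found")
})
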