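test_that("reservoir initialization matches its declared distributions", {
  cfg <- esnConfig(N = 100, sW = 0.1, omega = 2, seed = 5)
  esn <- initEsn(cfg)
  nz <- sum(esn$W != 0)
  expect_lt(abs(nz - 1000), 3 * sqrt(10000 * 0.1 * 0.9))  # binomial 3-sigma
  expect_true(all(abs(esn$W) <= 0.5))
  expect_true(all(abs(esn$Win) <= 1))  # 0.5 * omega
  expect_identical(initEsn(cfg)$W, esn$W)
  # omega = 0 zeroes the whole input matrix, bias column included
  esn0 <- initEsn(esnConfig(N = 20, omega = 0, seed = 2))
  expect_true(all(esn0$Win == 0))
})

test_that("spectral radius rescaling is exact and linear", {
  set.seed(8)
  W <- matrix(rnorm(900), 30, 30)
  W2 <- setSpectralRadius(W, 0.9)
  expect_equal(spectralRadius(W2), 0.9, tolerance = 1e-9)
  expect_equal(W2, W * (0.9 / spectralRadius(W)))
  expect_equal(setSpectralRadius(W, spectralRadius(W)), W, tolerance = 1e-12)
  expect_error(setSpectralRadius(matrix(0, 3, 3), 1), "nilpotent")
})

test_that("the effective spectral radius accounts for leaky integration", {
  set.seed(9)
  W <- matrix(rnorm(400), 20, 20)
  expect_equal(effectiveSpectralRadius(W, 1), spectralRadius(W))
  expect_equal(effectiveSpectralRadius(matrix(0, 5, 5), 0.4), 0.6)
  expect_equal(effectiveSpectralRadius(diag(c(0.5, -0.5)), 0.5), 0.75)
})

test_that("the state update follows the leaky tanh recursion", {
  cfg <- esnConfig(N = 4, omega = 0, alpha = 1, seed = 1)
  esn <- initEsn(cfg)
  esn$W <- matrix(0, 4, 4)
  esn$Win <- matrix(0, 4, 2)
  expect_equal(esnStep(esn, rep(0.3, 4), 1), rep(0, 4))
  esn$Win[, 1] <- 0.7  # bias only
  expect_equal(esnStep(esn, rep(0, 4), 0), rep(tanh(0.7), 4))
  half <- esn
  half$alpha <- 0.5
  expect_equal(esnStep(half, rep(0, 4), 0),
               0.5 * esnStep(esn, rep(0, 4), 0))
  expect_error(esnStep(esn, rep(0, 3), 0), "dimension")
  # compiled run agrees with the reference step and drops the washout
  cfg2 <- esnConfig(N = 10, omega = 1, alpha = 0.8, seed = 3)
  esn2 <- initEsn(cfg2)
  u <- runif(50, -1, 1)
  S <- esnRun(esn2, u, washout = 5)
  expect_equal(ncol(S), 45L)
  x <- numeric(10)
  for (t in 1:6) x <- esnStep(esn2, x, u[t])
  expect_equal(S[, 1], x, tolerance = 1e-12)
  expect_true(all(abs(S) <= 1))
  # zero input and zero bias leave the reservoir silent
  esn2$Win[] <- 0
  expect_true(all(esnRun(esn2, numeric(30)) == 0))
})

test_that("the Lyapunov estimate separates contracting and chaotic reservoirs", {
  # W = 0: the state forgets its past in one step
  cfg <- esnConfig(N = 10, omega = 0, alpha = 1, seed = 4)
  esn <- initEsn(cfg)
  esn$W <- matrix(0, 10, 10)
  esn$Win <- matrix(0, 10, 2)
  expect_lt(estimateLyapunov(esn), -5)
  # far beyond the stability boundary the autonomous exponent turns
  # positive (probeScale = 0: undriven reservoir)
  positives <- vapply(1:10, function(s) {
    e <- initEsn(esnConfig(N = 30, omega = 0, alpha = 1, seed = 400 + s))
    e$W <- setSpectralRadius(e$W, 2.5)
    estimateLyapunov(e, probeScale = 0) > 0
  }, NA)
  expect_gte(sum(positives), 9)
  # reproducibility to machine precision
  e <- initEsn(esnConfig(N = 50, seed = 77))
  expect_identical(estimateLyapunov(e), estimateLyapunov(e))
})

test_that("Lyapunov adjustment reaches its target and stops early when met", {
  cfg <- esnConfig(N = 50, alpha = 0.9, lambda0 = -0.2, seed = 20)
  adj <- adjustLyapunov(initEsn(cfg))
  expect_true(adj$converged)
  expect_lte(abs(adj$esn$lambdaHat + 0.2), 0.001)
  # rerunning on the adjusted network returns after a single estimate
  again <- adjustLyapunov(adj$esn)
  expect_equal(again$iterations, 1L)
  expect_equal(again$esn$W, adj$esn$W)
})

test_that("the adjustment trace replays the pseudocode decisions", {
  # independent hand-simulation of the iterative procedure, using the same
  # exponent measurements, radius moves and stopping rules
  esn <- initEsn(esnConfig(N = 40, alpha = 0.9, lambda0 = -0.1, seed = 33))
  lambda0 <- -0.1; tol <- 0.001; dRho <- 0.05; nMax <- 30L
  cur <- esn
  lams <- c(); devs <- c(); rhos <- c()
  for (i in seq_len(nMax)) {
    lams[i] <- estimateLyapunov(cur)
    devs[i] <- lams[i] - lambda0
    rhos[i] <- effectiveSpectralRadius(cur$W, cur$alpha)
    if (abs(devs[i]) <= tol ||
        (i > 1 && abs(devs[i]) == abs(devs[i - 1]))) break
    if (i > 1 && sign(devs[i]) != sign(devs[i - 1])) dRho <- dRho / 2
    target <- if (devs[i] > 0) rhos[i] - dRho else rhos[i] + dRho
    Wt <- cur$alpha * cur$W
    diag(Wt) <- diag(Wt) + (1 - cur$alpha)
    Wt <- setSpectralRadius(Wt, target)
    diag(Wt) <- diag(Wt) - (1 - cur$alpha)
    cur$W <- Wt / cur$alpha
  }
  adj <- adjustLyapunov(esn, lambda0 = -0.1)
  expect_equal(adj$iterations, length(lams))
  expect_equal(adj$trace$lambdaHat, lams, tolerance = 1e-12)
  expect_equal(adj$trace$rhoEff, rhos, tolerance = 1e-10)
  expect_equal(adj$esn$lambdaHat, lams[which.min(abs(devs))])
})

test_that("a higher Lyapunov target needs an equal or larger radius", {
  rhoFor <- function(target, s) {
    adj <- adjustLyapunov(initEsn(esnConfig(N = 40, lambda0 = target,
                                            seed = 600 + s)))
    adj$esn$rhoEff
  }
  diffs <- vapply(1:6, function(s) rhoFor(-0.05, s) - rhoFor(-0.2, s), 0)
  expect_gte(median(diffs), 0)
})

test_that("memory capacity respects its bounds and dies without input drive", {
  esn <- buildEsn(esnConfig(N = 30, omega = 1, alpha = 1, lambda0 = -0.2,
                            seed = 10))
  expect_gt(esn$MC, 0)
  expect_lte(esn$MC, 30 + 0.5)
  expect_identical(memoryCapacity(esn), memoryCapacity(esn))
  noDrive <- initEsn(esnConfig(N = 30, omega = 0, seed = 10))
  expect_lt(memoryCapacity(noDrive), 0.1)
})

test_that("input preprocessing normalizes and aligns with the tremor axis", {
  rec <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 2, seed = 2))
  pp <- preprocessInput(rec)
  expect_equal(IQR(pp$u), 1)
  expect_length(pp$u, floor(length(rec$x) / 2))
  expect_equal(pp$u * pp$iqr, pp$pc1)
  # a tremor fixed along 30 degrees dominates the band-passed variance,
  # so PC1 aligns with that axis
  fs <- 100
  t <- (0:2999) / fs
  ang <- 30 * pi / 180
  trem <- 3 * sin(2 * pi * 5 * t)
  slow <- cbind(65 * cos(2 * pi * 0.35 * t), 65 * sin(2 * pi * 0.35 * t))
  rec2 <- drawingRecording(x = 100 + slow[, 1] + trem * cos(ang) + rnorm(3000, 0, 0.05),
                           y = 100 + slow[, 2] + trem * sin(ang) + rnorm(3000, 0, 0.05),
                           samplingRate = fs, templateCenter = c(100, 100))
  pp2 <- preprocessInput(rec2)
  got <- atan2(pp2$loading[2], pp2$loading[1]) * 180 / pi
  expect_lt(abs(got - 30), 5)
  # collapsed trajectory is rejected
  flat <- drawingRecording(x = rep(100, 2000), y = rep(100, 2000))
  expect_error(preprocessInput(flat), "degenerate")
})

test_that("activation features summarize the reservoir response as 4N values", {
  esn <- buildEsn(esnConfig(N = 20, omega = 1, alpha = 0.9, lambda0 = -0.2,
                            seed = 6))
  rec <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 1.5,
                                       seed = 8))
  af <- activationFeatures(esn, rec)
  expect_length(af$d, 80L)
  expect_identical(names(af$d)[c(1, 21, 41, 61)],
                   c("rms_001", "sd_001", "wp_001", "wr_001"))
  expect_true(all(af$xRms >= 0))
  expect_true(all(af$xSd >= 0))
  # per-neuron algebraic identity: rms^2 = mean^2 + sd^2 (T-1)/T
  S <- esnRun(esn, preprocessInput(rec)$u)
  S <- S[, -(1:100)]
  T <- ncol(S)
  expect_equal(af$xRms^2,
               rowMeans(S)^2 + af$xSd^2 * (T - 1) / T,
               tolerance = 1e-10)
  # silent network yields zero activation summaries
  mute <- esn
  mute$Win[] <- 0
  afMute <- activationFeatures(mute, rec)
  expect_true(all(afMute$xRms == 0))
  expect_true(all(afMute$xSd == 0))
  # scaling the drawing scales the readout weights linearly
  rec2 <- rec
  rec2$x <- 100 + 3 * (rec$x - 100)
  rec2$y <- 100 + 3 * (rec$y - 100)
  af2 <- activationFeatures(esn, rec2)
  expect_equal(af2$wPred, 3 * af$wPred, tolerance = 1e-6)
  expect_equal(af2$wRec, 3 * af$wRec, tolerance = 1e-6)
})
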