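test_that("the combined spectrogram localizes a pure sinusoid", {
  fs <- 100
  rec <- makeCircleRecording(duration = 20,
                             xFun = function(t) 100 + sin(2 * pi * 5 * t),
                             yFun = function(t) rep(100, length(t)))
  sg <- combinedSpectrogram(rec)
  expect_equal(length(sg$frequencies), 256L)
  expect_equal(ncol(sg$power), floor((2000 - 512) / 5) + 1)
  peak <- sg$frequencies[which.max(rowMeans(sg$power))]
  expect_lt(abs(peak - 5), fs / 512 + 1e-12)  # within one bin width
  expect_true(all(sg$power >= 0))
  expect_false(is.unsorted(sg$frequencies))
})

test_that("the combined spectrogram is symmetric in x and y", {
  rec <- simulateDrawing(syntheticSpec(duration = 15, tremorAmp = 2, seed = 3))
  swapped <- rec
  swapped$x <- rec$y
  swapped$y <- rec$x
  expect_equal(combinedSpectrogram(rec)$power,
               combinedSpectrogram(swapped)$power)
})

test_that("an all-zero trajectory yields an all-zero power matrix", {
  rec <- makeCircleRecording(duration = 12,
                             xFun = function(t) numeric(length(t)),
                             yFun = function(t) numeric(length(t)))
  expect_true(all(combinedSpectrogram(rec)$power == 0))
  tiny <- drawingRecording(x = rnorm(300) + 100, y = rnorm(300) + 100)
  expect_error(combinedSpectrogram(tiny), "too short")
})

test_that("segmentation yields one segment per step with edge segments dropped", {
  rec <- makeCircleRecording(duration = 100)
  sg <- combinedSpectrogram(rec)
  seg <- segmentSpectra(sg)
  expect_equal(nrow(seg$S), ncol(sg$power) - 40L + 1L)
  # constant spectrogram: every segment PSD identical
  sg$power[] <- 1
  seg2 <- segmentSpectra(sg)
  expect_equal(max(apply(seg2$S, 2, function(v) diff(range(v)))), 0)
  # exactly 2 s of spectrogram: a single segment
  sg$power <- sg$power[, 1:40]
  sg$times <- sg$times[1:40]
  expect_equal(nrow(segmentSpectra(sg)$S), 1L)
})

test_that("background fitting recovers exact power laws and resists outliers", {
  f <- seq(0.2, 30, by = 0.2)
  fit <- fitBackground(3 * f^(-1.2), f)
  expect_equal(fit$b, 3, tolerance = 1e-6)
  expect_equal(fit$alpha, 1.2, tolerance = 1e-6)

  flat <- fitBackground(rep(2.5, length(f)), f)
  expect_equal(flat$alpha, 0)
  expect_equal(flat$b, 2.5, tolerance = 1e-9)

  rising <- fitBackground(0.1 * f^(1.5), f)  # alpha clipped at zero
  expect_equal(rising$alpha, 0)

  S <- 3 * f^(-1.2)
  iOut <- which.min(abs(f - 7))
  S[iOut] <- S[iOut] * 100
  clean <- fitBackground(3 * f^(-1.2), f)
  dirty <- fitBackground(S, f)
  expect_lt(abs(dirty$alpha - clean$alpha), 0.05)
})

test_that("tQ follows its defining ratio on constructed bin variances", {
  # spectra engineered so each 0.5 Hz bin holds known residual power
  f <- seq(2.25, 14.75, by = 0.5)
  equal <- tqFromSegment(rep(1, 26), f, b = 1, alpha = 0)
  expect_equal(equal$tQ, 1)
  spiked <- c(rep(1e-3, 25), 0.1)
  got <- tqFromSegment(spiked, f, b = 1, alpha = 0)
  expect_equal(got$tQ, 100)
  expect_equal(got$fTq, 14.75)
  degenerate <- tqFromSegment(rep(0, 26), f, b = 1, alpha = 0)
  expect_true(degenerate$degenerate)
  expect_true(is.na(degenerate$tQ))
})

test_that("tq series matches an unoptimized per-segment recomputation", {
  rec <- simulateDrawing(syntheticSpec(duration = 20, tremorAmp = 2,
                                       intermittency = 1, seed = 6))
  sg <- combinedSpectrogram(rec)
  seg <- segmentSpectra(sg)
  bg <- fitBackground(seg$S, seg$frequencies)
  series <- tqSeries(rec)
  expect_equal(nrow(series), nrow(seg$S))
  for (i in c(1L, 57L, nrow(seg$S))) {
    oracle <- oracleTq(seg$S[i, ], seg$frequencies, bg$b[i], bg$alpha[i])
    expect_equal(series$tQ[i], oracle$tQ, tolerance = 1e-10)
    expect_equal(series$f_tQ[i], oracle$fTq)
    one <- tqFromSegment(seg$S[i, ], seg$frequencies, bg$b[i], bg$alpha[i])
    expect_equal(one$tQ, oracle$tQ, tolerance = 1e-10)
    expect_equal(one$binVariances, oracle$binVariances, tolerance = 1e-12)
  }
})

test_that("tQ is invariant under trajectory scaling", {
  rec <- simulateDrawing(syntheticSpec(duration = 20, tremorAmp = 1.5,
                                       seed = 11))
  scaled <- rec
  scaled$x <- rec$templateCenter[1] + 3 * (rec$x - rec$templateCenter[1])
  scaled$y <- rec$templateCenter[2] + 3 * (rec$y - rec$templateCenter[2])
  a <- tqSeries(rec)
  b <- tqSeries(scaled)
  # the IRLS weights of the L1 background fit amplify rounding when
  # residuals hit the weight floor, so invariance is numerical, not bitwise
  expect_equal(b$tQ, a$tQ, tolerance = 1e-4)
  expect_equal(b$alpha, a$alpha, tolerance = 1e-4)
  expect_equal(b$b, 9 * a$b, tolerance = 1e-4)
})

test_that("a strong tremor pins the dominant bin and raises tQ", {
  withTrem <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 2,
                                            tremorFreq = 5.3,
                                            intermittency = 1, seed = 13))
  noTrem <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 0,
                                          seed = 13))
  a <- tqSeries(withTrem)
  b <- tqSeries(noTrem)
  expect_equal(nrow(a), nrow(b))
  # dominant bin sits at the 5.25 Hz bin centre for most segments
  expect_gt(mean(a$f_tQ == 5.25), 0.5)
  expect_gt(median(a$tQ), median(b$tQ))
  # determinism of the whole chain
  expect_identical(tqSeries(withTrem), a)
})

test_that("tQ of white-noise trajectories stays within a loose envelope", {
  set.seed(42)
  meds <- replicate(3, {
    rec <- drawingRecording(x = rnorm(2000) + 100, y = rnorm(2000) + 100,
                            templateCenter = c(100, 100))
    median(tqSeries(rec)$tQ)
  })
  expect_true(all(meds >= 0.5 & meds <= 5))
})

test_that("band power above 3 Hz obeys Parseval and amplitude scaling", {
  fs <- 100
  t <- (0:9999) / fs
  rec <- drawingRecording(x = 100 + sin(2 * pi * 5 * t), y = rep(100, 10000),
                          samplingRate = fs, templateCenter = c(100, 100))
  bp <- psdPowerAbove3Hz(rec)
  expect_equal(bp$power, 0.5, tolerance = 0.02)  # unit sinusoid power
  expect_equal(bp$log10Power, log10(bp$power))

  still <- drawingRecording(x = rep(100, 10000), y = rep(100, 10000),
                            samplingRate = fs)
  expect_lt(psdPowerAbove3Hz(still)$power, 1e-12)

  a1 <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 1,
                                      intermittency = 1, jitterSd = 0,
                                      seed = 9))
  a2 <- simulateDrawing(syntheticSpec(duration = 30, tremorAmp = 2,
                                      intermittency = 1, jitterSd = 0,
                                      seed = 9))
  ratio <- psdPowerAbove3Hz(a2)$power / psdPowerAbove3Hz(a1)$power
  expect_equal(ratio, 4, tolerance = 0.1 * 4)
})
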