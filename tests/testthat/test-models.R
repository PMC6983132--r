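test_that("stratified splitting allocates 60% of each stratum to training", {
  scores <- rep(0:10, each = 10)
  sp <- stratifiedSplit(scores, 0.6, seed = 1)
  expect_setequal(c(sp$train, sp$test), seq_along(scores))
  expect_length(intersect(sp$train, sp$test), 0)
  for (s in 0:10)
    expect_equal(sum(scores[sp$train] == s), 6)
  expect_identical(stratifiedSplit(scores, 0.6, seed = 1)$train, sp$train)
  expect_false(identical(stratifiedSplit(scores, 0.6, seed = 2)$train,
                         sp$train))
  # singleton strata merge into the nearest score before splitting
  rare <- c(rep(2, 10), 7)
  spRare <- stratifiedSplit(rare, 0.6, seed = 3)
  expect_length(spRare$train, 7)  # merged stratum of 11: round(6.6) = 7
})

test_that("LASSO recovers a planted sparse linear model", {
  set.seed(5)
  n <- 200
  D <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("p", 1:10)))
  y <- 2 * D[, 3] - 1.5 * D[, 7] + 5
  model <- fitLasso(D, y, lambdaChoice = "min", scaleBounds = c(-50, 50),
                    seed = 2)
  nz <- names(model$coefficients)[model$coefficients != 0]
  expect_true(all(c("p3", "p7") %in% nz))
  pred <- predict(model, D)
  expect_gt(cor(pred, y)^2, 0.99)
  # the 1-SE model is never denser than the minimum-MSE model
  expect_lte(model$nonzeroCounts[["1se"]], model$nonzeroCounts[["min"]])
  expect_lte(model$lambdaMin, model$lambda1se)
})

test_that("pure-noise targets shrink to a near-intercept model", {
  set.seed(9)
  D <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("p", 1:8)))
  y <- rnorm(60)
  model <- fitLasso(D, y, lambdaChoice = "1se", scaleBounds = c(-10, 10),
                    seed = 4)
  expect_lte(sum(model$coefficients != 0), 1)
  pred <- predict(model, D)
  expect_lt(diff(range(pred)), 0.75)
  expect_lt(abs(mean(pred) - mean(y)), 0.25)
})

test_that("constant columns are dropped with a warning", {
  set.seed(3)
  D <- cbind(flat = rep(2, 40), ok = rnorm(40), ok2 = rnorm(40))
  y <- D[, "ok"] + rnorm(40, 0, 0.1)
  expect_warning(model <- fitLasso(D, y, scaleBounds = c(-10, 10)),
                 "constant column")
  expect_false("flat" %in% names(model$coefficients))
})

test_that("the limiting function is identity on-range and saturates off-range", {
  expect_identical(limitOutput(5, 0, 10), 5)
  expect_identical(limitOutput(c(0, 10), 0, 10), c(0, 10))
  expect_equal(limitOutput(12, 0, 10), 10 + 0.5 * tanh(2))
  expect_equal(limitOutput(-3, 0, 10), 0 + 0.5 * tanh(-3))
  y <- seq(-100, 100, by = 0.37)
  g <- limitOutput(y, 0, 10)
  expect_true(all(g >= -0.5 & g <= 10.5))  # tanh saturates to 1 in floats
  expect_true(all(diff(g) >= 0))           # monotone
  g4 <- limitOutput(y, 0, 4)
  expect_true(all(g4 >= -0.5 & g4 <= 4.5))
})

test_that("prediction is the limited linear functional of the features", {
  model <- structure(list(coefficients = c(a = 2, b = -1), intercept = 0.5,
                          scaleBounds = c(0, 10),
                          provenance = c(a = "TS", b = "TS")),
                     class = "ScoreModel")
  D <- matrix(c(3, 1), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(predict(model, D), 0.5 + 2 * 3 - 1 * 1)
  # all-zero coefficients give the constant limited intercept
  model$coefficients[] <- 0
  model$intercept <- 12
  expect_equal(predict(model, D), 10 + 0.5 * tanh(2))
  expect_error(predict(model, D[, 1, drop = FALSE]), "lacks model columns")
})

test_that("the hyperparameter grid has the designed cardinalities", {
  g <- ensembleGrid()
  expect_equal(nrow(g), 216L)
  expect_equal(nrow(unique(g[, c("N", "lambda0", "alpha", "omega")])), 54L)
  expect_equal(nrow(ensembleGrid(N = 50)), 72L)
  expect_equal(nrow(ensembleGrid(N = 50, nRep = 1)), 18L)
  expect_true(all(g$sW == 0.1))
})

test_that("correlation evaluation matches hand computation with Fisher CI", {
  expect_equal(evaluatePredictions(1:10, 1:10)$r, 1)
  expect_equal(evaluatePredictions(1:10, -(1:10))$r, -1)
  ev <- evaluatePredictions(c(0, 1, 2, 3), c(0, 2, 1, 3))
  expect_equal(ev$r, 0.8)
  expect_equal(ev$ci,
               tanh(atanh(0.8) + qnorm(c(0.025, 0.975)) * 1 / sqrt(4 - 3)))
  expect_error(evaluatePredictions(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(evaluatePredictions(1:2, 1:2), "at least 3")
})

test_that("parameter inclusion counts nonzero coefficients by group", {
  cf <- c(PSDc_var_3Hz = 1.2, avg_tQ_max = 0, rms_001 = -0.3, wp_002 = 0.1,
          wr_001 = 0)
  prov <- c(PSDc_var_3Hz = "TS", avg_tQ_max = "TS", rms_001 = "ESN:x_rms",
            wp_002 = "ESN:w@+1", wr_001 = "ESN:w@-MC/2")
  model <- structure(list(coefficients = cf, provenance = prov),
                     class = "ScoreModel")
  inc <- parameterInclusion(model)
  expect_equal(inc$count[inc$group == "TS"], 1)
  expect_equal(inc$count[inc$group == "ESN:x_rms"], 1)
  expect_equal(inc$count[inc$group == "ESN:w@-MC/2"], 0)
  expect_equal(sum(inc$percent), 100, tolerance = 1e-9)
  # brute-force recount
  expect_equal(sum(inc$count), sum(cf != 0))
  # intercept-only model
  model$coefficients[] <- 0
  inc0 <- parameterInclusion(model)
  expect_true(all(inc0$count == 0))
})

test_that("small ensembles aggregate by the member mean within member range", {
  ds <- simulateDataset(36, seed = 44, baseSpec = syntheticSpec(duration = 20))
  y <- ds$ratings$tremor_score
  sp <- stratifiedSplit(y, 0.6, seed = 1)
  fvs <- lapply(ds$recordings, extractFeatures)
  DTS <- assembleMatrix(tsFeatures = fvs)
  grid <- ensembleGrid(N = 15L, lambda0 = -0.2, alpha = 1, omega = 1,
                       nRep = 2L)
  ens <- buildEnsemble(ds$recordings, y, sp, grid = grid, kind = "esn_ts",
                       DTS = DTS, seed = 7)
  expect_length(ens$members, 2L)
  expect_equal(ens$prediction, colMeans(ens$testPredictions))
  expect_true(all(ens$prediction >= apply(ens$testPredictions, 2, min) - 1e-12))
  expect_true(all(ens$prediction <= apply(ens$testPredictions, 2, max) + 1e-12))
  expect_true(all(ens$prediction > -0.5 & ens$prediction < 10.5))
  # predict() on the training recordings reproduces member averaging
  predTrain <- predict(ens, ds$recordings[sp$train], DTS = DTS[sp$train, ])
  expect_length(predTrain, length(sp$train))
  expect_true(all(is.finite(predTrain)))
})
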