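#' Stratified train/test split
#'
#' Allocates `round(trainFraction * n_s)` of the recordings of each score
#' stratum to training, by random sampling within the stratum, so score
#' proportions are preserved. Strata with fewer than 2 recordings are
#' merged with the nearest represented score (ties toward the lower score)
#' before splitting.
#'
#' @param scores integer score per recording.
#' @param trainFraction fraction of rows assigned to training.
#' @param seed RNG seed.
#' @return object of class `SplitPlan`: list with `train`, `test` (disjoint,
#'   exhaustive index vectors) and `strata` (the merged stratum label per
#'   recording).
#' @export
stratifiedSplit <- function(scores, trainFraction = 0.6, seed = 1L) {
  n <- length(scores)
  if (n == 0) stop("empty dataset")
  tab <- table(scores)
  levelsRep <- as.numeric(names(tab))
  strata <- as.numeric(scores)
  small <- levelsRep[tab < 2]
  for (s in small) {
    others <- setdiff(unique(strata), s)
    if (!length(others)) break
    nearest <- others[order(abs(others - s), others)][1]
    strata[strata == s] <- nearest
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  train <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    k <- round(trainFraction * length(idx))
    k <- max(1L, min(length(idx) - 1L, k))
    train <- c(train, sample(idx, k))
  }
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 strata = strata, trainFraction = trainFraction),
            class = "SplitPlan")
}

# stratified fold assignment: shuffle within score groups, deal folds
# cyclically
.stratFolds <- function(y, nFolds) {
  fold <- integer(length(y))
  offset <- 0L
  for (s in unique(y)) {
    idx <- sample(which(y == s))
    fold[idx] <- ((seq_along(idx) + offset - 1L) %% nFolds) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Fit a LASSO score model
#'
#' Fits the LASSO path on standardized columns (via [glmnet::glmnet()];
#' coefficients are returned on the original scale) and chooses the
#' regularization parameter by 10-time, 5-fold cross-validation: 10
#' independent stratified 5-fold partitions, with the mean and standard
#' error of the CV MSE computed across all 50 fold-level MSEs.
#' `lambda_MIN` minimizes the mean CV MSE; `lambda_1SE` is the largest
#' lambda whose mean CV MSE does not exceed that minimum plus its standard
#' error (the sparsest acceptable model). Constant columns are dropped with
#' a warning.
#'
#' @param D feature matrix (rows = recordings), e.g. from
#'   [assembleMatrix()].
#' @param y numeric scores.
#' @param lambdaChoice `"min"` or `"1se"`.
#' @param scaleBounds `(y_min, y_max)` of the modelled scale: `c(0, 10)`
#'   for the 0--10 tremor score, `c(0, 4)` for UPDRS item 21.
#' @param seed RNG seed for the CV partitions.
#' @param nRepeats,nFolds cross-validation design.
#' @return object of class `ScoreModel`: named full coefficient vector,
#'   `intercept`, `lambdaChoice`, `lambdaValue`, `scaleBounds`,
#'   `provenance`, `nonzeroCounts` (at both lambda choices) and the CV
#'   summary `cv` (`lambda`, `mean`, `se`).
#' @export
fitLasso <- function(D, y, lambdaChoice = c("min", "1se"),
                     scaleBounds = c(0, 10), seed = 1L, nRepeats = 10L,
                     nFolds = 5L) {
  lambdaChoice <- match.arg(lambdaChoice)
  if (nrow(D) != length(y)) stop("rows of D must match length of y")
  if (nrow(D) < 20L) stop("need at least 20 rows to fit a score model")
  if (nrow(D) < nFolds) stop("fewer rows than folds")
  prov <- attr(D, "provenance")
  if (is.null(prov)) prov <- rep("TS", ncol(D))
  names(prov) <- colnames(D)
  constant <- apply(D, 2L, function(v) max(v) - min(v) == 0)
  if (any(constant)) {
    warning("dropping constant column(s): ",
            paste(colnames(D)[constant], collapse = ", "))
    D <- D[, !constant, drop = FALSE]
    prov <- prov[!constant]
  }

  full <- glmnet::glmnet(D, y, family = "gaussian", standardize = TRUE)
  lambda <- full$lambda

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  mseRows <- matrix(NA_real_, nRepeats * nFolds, length(lambda))
  row <- 0L
  for (rep in seq_len(nRepeats)) {
    fold <- .stratFolds(y, nFolds)
    for (f in seq_len(nFolds)) {
      row <- row + 1L
      hold <- fold == f
      fit <- glmnet::glmnet(D[!hold, , drop = FALSE], y[!hold],
                            family = "gaussian", standardize = TRUE,
                            lambda = lambda)
      pred <- predict(fit, D[hold, , drop = FALSE], s = lambda)
      mseRows[row, ] <- colMeans((pred - y[hold])^2)
    }
  }
  cvMean <- colMeans(mseRows)
  cvSe <- apply(mseRows, 2L, sd) / sqrt(nrow(mseRows))
  iMin <- which.min(cvMean)
  lambdaMin <- lambda[iMin]
  ok <- which(cvMean <= cvMean[iMin] + cvSe[iMin])
  lambda1se <- max(lambda[ok])
  chosen <- if (lambdaChoice == "min") lambdaMin else lambda1se

  coefAt <- function(s) {
    cf <- as.numeric(coef(full, s = s, exact = FALSE))
    setNames(cf, c("(Intercept)", colnames(D)))
  }
  cf <- coefAt(chosen)
  nz <- function(s) sum(coefAt(s)[-1L] != 0)

  structure(list(coefficients = cf[-1L], intercept = cf[1L],
                 lambdaChoice = lambdaChoice, lambdaValue = chosen,
                 lambdaMin = lambdaMin, lambda1se = lambda1se,
                 scaleBounds = scaleBounds, provenance = prov,
                 nonzeroCounts = c(min = nz(lambdaMin), `1se` = nz(lambda1se)),
                 cv = data.frame(lambda = lambda, mean = cvMean, se = cvSe)),
            class = "ScoreModel")
}

#' @export
print.ScoreModel <- function(x, ...) {
  cat(sprintf("ScoreModel (lambda_%s = %.4g): %d/%d nonzero coefficients, bounds [%g, %g]\n",
              toupper(x$lambdaChoice), x$lambdaValue,
              sum(x$coefficients != 0), length(x$coefficients),
              x$scaleBounds[1], x$scaleBounds[2]))
  invisible(x)
}

#' Bounded score output
#'
#' Smooth limiting of a linear predictor to the modelled scale: the
#' identity on `[yMin, yMax]` and a `0.5 tanh` saturation outside, so
#' predictions lie strictly within `(yMin - 0.5, yMax + 0.5)`.
#'
#' @param y raw prediction(s).
#' @param yMin,yMax scale bounds, `yMin < yMax`.
#' @return limited prediction(s).
#' @export
limitOutput <- function(y, yMin, yMax) {
  stopifnot(yMin < yMax)
  out <- y
  hi <- y > yMax
  lo <- y < yMin
  out[hi] <- yMax + 0.5 * tanh(y[hi] - yMax)
  out[lo] <- yMin + 0.5 * tanh(y[lo] - yMin)
  out
}

#' Predict continuous scores
#'
#' Linear predictor of the fitted coefficients followed by the bounded
#' output transform.
#'
#' @param object a [fitLasso()] model.
#' @param newdata feature matrix containing all model columns.
#' @param ... unused.
#' @return numeric vector of limited continuous scores.
#' @export
predict.ScoreModel <- function(object, newdata, ...) {
  cols <- names(object$coefficients)
  missing <- setdiff(cols, colnames(newdata))
  if (length(missing))
    stop("newdata lacks model columns: ", paste(head(missing, 5), collapse = ", "))
  eta <- object$intercept +
    as.numeric(newdata[, cols, drop = FALSE] %*% object$coefficients)
  limitOutput(eta, object$scaleBounds[1], object$scaleBounds[2])
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param pred,target paired numeric vectors (>= 3 pairs, non-constant).
#' @param conf confidence level.
#' @return list with `r`, `ci` (length 2) and `n`.
#' @export
evaluatePredictions <- function(pred, target, conf = 0.95) {
  n <- length(pred)
  if (n < 3L) stop("need at least 3 pairs")
  if (sd(pred) == 0 || sd(target) == 0) stop("zero-variance input")
  r <- cor(pred, target)
  z <- atanh(r)
  zc <- qnorm(1 - (1 - conf) / 2)
  se <- 1 / sqrt(n - 3)
  list(r = r, ci = tanh(c(z - zc * se, z + zc * se)), n = n)
}

#' Parameter inclusion by provenance group
#'
#' Counts the nonzero coefficients of a model (or, summed, of an
#' ensemble's members) per provenance group — the 23 time-series parameters
#' and the four reservoir-summary blocks — and expresses them as
#' percentages of all included parameters.
#'
#' @param model a `ScoreModel` or `ModelEnsemble`.
#' @return data.frame with `group`, `count`, `percent`.
#' @export
parameterInclusion <- function(model) {
  groups <- c("TS", "ESN:x_rms", "ESN:x_sd", "ESN:w@+1", "ESN:w@-MC/2")
  countOne <- function(m) {
    nz <- names(m$coefficients)[m$coefficients != 0]
    tab <- table(factor(unname(m$provenance[nz]), levels = groups))
    as.numeric(tab)
  }
  counts <- if (inherits(model, "ModelEnsemble")) {
    Reduce(`+`, lapply(model$members, countOne))
  } else countOne(model)
  total <- sum(counts)
  data.frame(group = groups, count = counts,
             percent = if (total > 0) 100 * counts / total else rep(0, 5))
}

#' Hyperparameter grid of the reservoir ensemble
#'
#' Cartesian product of the ensemble hyperparameters times `nRep`
#' repetitions with freshly initialized reservoirs. The full grid — sizes
#' \{50, 100, 200\}, Lyapunov targets \{-0.2, -0.05\}, leaking rates
#' \{0.6, 0.9, 1\}, input scalings \{0.1, 1, 10\}, 4 repetitions — yields
#' 216 member models.
#'
#' @param N,lambda0,alpha,omega hyperparameter value sets.
#' @param nRep repetitions per hyperparameter combination.
#' @param sW reservoir sparsity.
#' @return data.frame with one row per ensemble member (`member`, `N`,
#'   `lambda0`, `alpha`, `omega`, `rep`, `sW`).
#' @export
ensembleGrid <- function(N = c(50L, 100L, 200L), lambda0 = c(-0.2, -0.05),
                         alpha = c(0.6, 0.9, 1), omega = c(0.1, 1, 10),
                         nRep = 4L, sW = 0.1) {
  g <- expand.grid(rep = seq_len(nRep), omega = omega, alpha = alpha,
                   lambda0 = lambda0, N = N,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("N", "lambda0", "alpha", "omega", "rep")]
  g <- g[order(g$N, g$lambda0, g$alpha, g$omega, g$rep), ]
  rownames(g) <- NULL
  cbind(member = seq_len(nrow(g)), g, sW = sW)
}

#' Build and fit a reservoir model ensemble
#'
#' One member per grid row: a fresh reservoir is constructed
#' ([buildEsn()]), every recording's preprocessed input is run through it
#' to produce the `4N` activation parameters, and a LASSO score model is
#' fitted on the training rows of the member's feature matrix (`D_ESN`, or
#' `D_ESN+TS` when `DTS` is supplied and `kind = "esn_ts"`). The
#' signal-based parameters are computed once and reused across members;
#' only the reservoirs are re-initialized. The ensemble prediction is the
#' arithmetic mean of the members' (already limited) predictions.
#'
#' @param recordings list of [drawingRecording()] (or precomputed
#'   [preprocessInput()] results).
#' @param y numeric scores, one per recording.
#' @param split a [stratifiedSplit()] plan.
#' @param grid an [ensembleGrid()].
#' @param kind `"esn"` or `"esn_ts"`.
#' @param DTS the 23-column time-series matrix (required for
#'   `kind = "esn_ts"`).
#' @param lambdaChoice,scaleBounds passed to [fitLasso()].
#' @param seed master seed; member reservoir seeds are derived from it.
#' @return object of class `ModelEnsemble`: `members` (ScoreModels),
#'   `memberEsns`, `grid`, `testPredictions` (members x test rows),
#'   `prediction` (ensemble mean on the test rows), `testIndex`.
#' @export
buildEnsemble <- function(recordings, y, split, grid = ensembleGrid(),
                          kind = c("esn", "esn_ts"), DTS = NULL,
                          lambdaChoice = "min", scaleBounds = c(0, 10),
                          seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "esn_ts" && is.null(DTS))
    stop("kind = 'esn_ts' requires the time-series matrix DTS")
  pp <- lapply(recordings, function(r)
    if (inherits(r, "DrawingRecording")) preprocessInput(r) else r)
  nRec <- length(pp)
  members <- vector("list", nrow(grid))
  esns <- vector("list", nrow(grid))
  preds <- matrix(NA_real_, nrow(grid), length(split$test))
  for (m in seq_len(nrow(grid))) {
    cfg <- esnConfig(N = grid$N[m], sW = grid$sW[m], omega = grid$omega[m],
                     alpha = grid$alpha[m], lambda0 = grid$lambda0[m],
                     seed = (as.integer(seed) + 104729L * m) %% 2147483647L)
    esn <- buildEsn(cfg)
    dList <- lapply(pp, function(p) activationFeatures(esn, p)$d)
    DESN <- assembleMatrix(esnFeatures = dList)
    D <- if (kind == "esn_ts") {
      M <- cbind(DTS, DESN)
      attr(M, "provenance") <- c(attr(DTS, "provenance"),
                                 attr(DESN, "provenance"))
      M
    } else DESN
    model <- fitLasso(D[split$train, , drop = FALSE], y[split$train],
                      lambdaChoice = lambdaChoice,
                      scaleBounds = scaleBounds,
                      seed = (as.integer(seed) + 15485863L * m) %% 2147483647L)
    members[[m]] <- model
    esns[[m]] <- esn
    preds[m, ] <- predict(model, D[split$test, , drop = FALSE])
  }
  structure(list(members = members, memberEsns = esns, grid = grid,
                 kind = kind, testPredictions = preds,
                 prediction = colMeans(preds), testIndex = split$test),
            class = "ModelEnsemble")
}

#' @export
print.ModelEnsemble <- function(x, ...) {
  cat(sprintf("ModelEnsemble (%s): %d members, %d test predictions\n",
              x$kind, length(x$members), length(x$prediction)))
  invisible(x)
}

#' Predict with a model ensemble
#'
#' Runs new recordings through every member's reservoir, predicts with the
#' member's score model, and averages the limited member predictions.
#'
#' @param object a [buildEnsemble()] ensemble.
#' @param newRecordings list of recordings (or preprocessed inputs).
#' @param DTS time-series matrix for the new recordings (for `esn_ts`
#'   ensembles).
#' @param ... unused.
#' @return numeric vector of ensemble scores.
#' @export
predict.ModelEnsemble <- function(object, newRecordings, DTS = NULL, ...) {
  if (object$kind == "esn_ts" && is.null(DTS))
    stop("esn_ts ensemble requires DTS for the new recordings")
  pp <- lapply(newRecordings, function(r)
    if (inherits(r, "DrawingRecording")) preprocessInput(r) else r)
  preds <- vapply(seq_along(object$members), function(m) {
    esn <- object$memberEsns[[m]]
    dList <- lapply(pp, function(p) activationFeatures(esn, p)$d)
    DESN <- assembleMatrix(esnFeatures = dList)
    D <- if (object$kind == "esn_ts") cbind(DTS, DESN) else DESN
    predict(object$members[[m]], D)
  }, numeric(length(pp)))
  rowMeans(matrix(preds, nrow = length(pp)))
}
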