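#' Transverse (radial) drawing velocity
#'
#' The velocity component transverse to the reference circle, read as the
#' radial direction relative to the template centre: motion along the
#' template is tangential, so tremor shows up as radial excursion. The
#' finite-difference velocity (central differences at interior points,
#' one-sided at the ends) is projected onto the unit vector from the
#' template centre to the pen position; if the pen sits exactly at the
#' centre the previous direction is carried.
#'
#' @param rec a [drawingRecording()] with known template centre.
#' @return numeric vector `V_t` in mm/s, same length as the recording.
#' @export
transverseVelocity <- function(rec) {
  n <- length(rec$x)
  fs <- rec$samplingRate
  d <- function(v) {
    dv <- numeric(n)
    dv[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / 2
    dv[1] <- v[2] - v[1]
    dv[n] <- v[n] - v[n - 1]
    dv * fs
  }
  vx <- d(rec$x); vy <- d(rec$y)
  rx <- rec$x - rec$templateCenter[1]
  ry <- rec$y - rec$templateCenter[2]
  r <- sqrt(rx^2 + ry^2)
  zero <- which(r == 0)
  if (length(zero)) {
    for (i in zero) {
      j <- if (i > 1) i - 1L else which(r > 0)[1]
      if (is.na(j) || r[j] == 0) { rx[i] <- 1; ry[i] <- 0; r[i] <- 1 }
      else { rx[i] <- rx[j]; ry[i] <- ry[j]; r[i] <- r[j] }
    }
  }
  (vx * rx + vy * ry) / r
}

#' Names of the 23 time-series parameters
#'
#' Fixed schema of the per-recording feature vector; the four `_log` columns
#' are base-10 logarithms of their source parameters (the columns whose raw
#' distributions are heavily right-skewed) and the `cv_` columns are
#' sd/mean ratios.
#' @return character vector of length 23.
#' @export
featureNames <- function() c(
  "PSDc_var_3Hz", "PSDc_var_3Hz_log",
  "f_tQ_mod", "abs_f_tQ_dist_5Hz",
  "avg_tQ_max", "avg_tQ_max_log", "sd_tQ_max", "sd_tQ_max_log", "cv_tQ_max",
  "avg_alpha", "sd_alpha", "cv_alpha",
  "avg_abs_Vt.LP.1", "sd_abs_Vt.LP.1", "sd_abs_Vt.LP.1_log",
  "cv_abs_Vt.LP.1",
  "avg_press", "sd_press", "cv_press",
  "Vt.HP.C5_MSEn_2_5", "Vt.HP.C5_MSEn_2_10", "Vt.HP.C5_MSEn_2_25",
  "Vt.HP.C5_MSEn_2_50")

#' Extract the 23 time-series parameters of a recording
#'
#' Computes the full expert feature vector:
#' * `PSDc_var_3Hz(_log)` — trajectory band power above 3 Hz
#'   ([psdPowerAbove3Hz()]);
#' * `f_tQ_mod` — modal bin centre of the per-segment dominant frequencies
#'   `f_tQ` (ties toward the lower frequency), and its absolute distance
#'   from 5 Hz;
#' * `avg/sd/cv_tQ_max(_log)` — statistics of tQ over the segments covering
#'   the 10 s of measurement with the highest tQ (200 segments at the
#'   0.05 s segment step; if fewer segments exist, all are used and the
#'   vector is flagged);
#' * `avg/sd/cv_alpha` — statistics of the fitted background exponent over
#'   all segments;
#' * `avg/sd/cv_abs_Vt.LP.1(_log)` — statistics of the absolute transverse
#'   velocity low-passed at 1 Hz (zero-phase 501-tap Hann FIR);
#' * `avg/sd/cv_press` — raw pen pressure statistics;
#' * `Vt.HP.C5_MSEn_2_{5,10,25,50}` — multiscale entropy (m = 2) of the
#'   transverse velocity high-passed at 0.05 Hz (zero-phase Hann FIR,
#'   order 2000).
#'
#' @param rec a [drawingRecording()].
#' @param msenTaus entropy scales.
#' @param msenRFactor entropy threshold as a fraction of the signal SD.
#' @return named numeric vector of length 23 (class `FeatureVector`), with
#'   attribute `flags` listing any quality flags (imputed pressure, fewer
#'   than 200 segments, infinite entropy sentinels).
#' @export
extractFeatures <- function(rec, msenTaus = c(5L, 10L, 25L, 50L),
                            msenRFactor = 0.15) {
  fs <- rec$samplingRate
  flags <- character()
  out <- setNames(numeric(23), featureNames())

  bp <- psdPowerAbove3Hz(rec)
  out["PSDc_var_3Hz"] <- bp$power
  out["PSDc_var_3Hz_log"] <- bp$log10Power

  tq <- tqSeries(rec)
  ok <- !tq$degenerate
  if (!any(ok)) stop("all segments have degenerate residual spectra")
  centers <- tqBinCenters()
  counts <- table(factor(tq$f_tQ[ok], levels = centers))
  mode <- centers[which.max(counts)]
  out["f_tQ_mod"] <- mode
  out["abs_f_tQ_dist_5Hz"] <- abs(mode - 5)

  nTop <- 200L
  if (sum(ok) < nTop) {
    nTop <- sum(ok)
    flags <- c(flags, "fewer_than_200_segments")
  }
  top <- sort(tq$tQ[ok], decreasing = TRUE)[seq_len(nTop)]
  out["avg_tQ_max"] <- mean(top)
  out["avg_tQ_max_log"] <- log10(mean(top))
  out["sd_tQ_max"] <- sd(top)
  out["sd_tQ_max_log"] <- log10(sd(top))
  out["cv_tQ_max"] <- sd(top) / mean(top)

  out["avg_alpha"] <- mean(tq$alpha)
  out["sd_alpha"] <- sd(tq$alpha)
  out["cv_alpha"] <- sd(tq$alpha) / mean(tq$alpha)

  vt <- transverseVelocity(rec)
  lp <- designFir(500L, 1, fs, type = "low")
  aVtLp <- abs(zeroPhaseFilter(lp, vt))
  out["avg_abs_Vt.LP.1"] <- mean(aVtLp)
  out["sd_abs_Vt.LP.1"] <- sd(aVtLp)
  out["sd_abs_Vt.LP.1_log"] <- log10(sd(aVtLp))
  out["cv_abs_Vt.LP.1"] <- sd(aVtLp) / mean(aVtLp)

  out["avg_press"] <- mean(rec$pressure)
  out["sd_press"] <- sd(rec$pressure)
  out["cv_press"] <- sd(rec$pressure) / mean(rec$pressure)
  if (isTRUE(rec$pressureImputed)) flags <- c(flags, "pressure_imputed")

  hp <- designFir(2000L, 0.05, fs, type = "high")
  vtHp <- zeroPhaseFilter(hp, vt)
  for (tau in msenTaus) {
    val <- multiscaleEntropy(vtHp, m = 2L, rFactor = msenRFactor, tau = tau)
    if (!is.null(attr(val, "flag")))
      flags <- c(flags, paste0("msen_", tau, "_", attr(val, "flag")))
    out[paste0("Vt.HP.C5_MSEn_2_", tau)] <- as.numeric(val)
  }

  structure(out, flags = flags, class = c("FeatureVector", "numeric"))
}

#' Assemble a feature matrix
#'
#' Binds per-recording feature vectors into a recordings x parameters
#' matrix with a provenance tag per column group (`TS` for the 23
#' time-series parameters; `ESN:x_rms`, `ESN:x_sd`, `ESN:w@+1`,
#' `ESN:w@-MC/2` for reservoir summaries, as produced by
#' [activationFeatures()]). Infinite entropy sentinels are substituted by
#' the largest finite value observed in their column (regularized linear
#' models cannot ingest infinities); if a column has no finite value it is
#' set to 0.
#'
#' @param tsFeatures list of [extractFeatures()] vectors, or `NULL`.
#' @param esnFeatures list of [activationFeatures()] `d` vectors (length
#'   4N), or `NULL`.
#' @param ids optional row names.
#' @return numeric matrix with attribute `provenance` (character, one tag
#'   per column).
#' @export
assembleMatrix <- function(tsFeatures = NULL, esnFeatures = NULL, ids = NULL) {
  parts <- list()
  prov <- character()
  if (!is.null(tsFeatures)) {
    M <- do.call(rbind, lapply(tsFeatures, as.numeric))
    colnames(M) <- featureNames()
    parts <- c(parts, list(M))
    prov <- c(prov, rep("TS", ncol(M)))
  }
  if (!is.null(esnFeatures)) {
    M <- do.call(rbind, esnFeatures)
    if (is.null(colnames(M))) stop("ESN feature vectors must be named")
    parts <- c(parts, list(M))
    groups <- c(rms = "ESN:x_rms", sd = "ESN:x_sd", wp = "ESN:w@+1",
                wr = "ESN:w@-MC/2")
    prov <- c(prov, unname(groups[sub("_.*$", "", colnames(M))]))
  }
  if (!length(parts)) stop("no features supplied")
  n <- unique(vapply(parts, nrow, 1L))
  if (length(n) != 1L) stop("feature blocks have differing row counts")
  D <- do.call(cbind, parts)
  if (anyDuplicated(colnames(D))) stop("duplicate column names")
  for (j in seq_len(ncol(D))) {
    inf <- !is.finite(D[, j])
    if (any(inf)) {
      finite <- D[is.finite(D[, j]), j]
      D[inf, j] <- if (length(finite)) max(finite) else 0
    }
  }
  if (!is.null(ids)) rownames(D) <- ids
  attr(D, "provenance") <- prov
  D
}

#' Skewness screening diagnostic
#'
#' The one-off procedure that selected the log-transformed parameters:
#' skewness of each column is computed on `nSubsets` random subsets of
#' `fraction` of the rows, and a column is flagged when its mean skewness
#' minus one SD exceeds `threshold`. Provided as a diagnostic; the package's
#' feature schema keeps the four log columns fixed rather than re-deriving
#' them per dataset.
#'
#' @param D feature matrix.
#' @param nSubsets number of random subsets.
#' @param fraction subset fraction of rows.
#' @param threshold flagging threshold on mean skewness minus SD.
#' @param seed RNG seed.
#' @return data.frame with per-column mean skewness, SD and `flagged`.
#' @export
skewnessScreen <- function(D, nSubsets = 100L, fraction = 0.6,
                           threshold = 3, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  skew <- function(v) {
    v <- v - mean(v)
    mean(v^3) / (mean(v^2)^1.5)
  }
  n <- nrow(D)
  k <- max(2L, round(fraction * n))
  sk <- matrix(NA_real_, nSubsets, ncol(D))
  for (i in seq_len(nSubsets)) {
    rows <- sample.int(n, k)
    sk[i, ] <- apply(D[rows, , drop = FALSE], 2L, skew)
  }
  m <- colMeans(sk)
  s <- apply(sk, 2L, sd)
  data.frame(parameter = colnames(D), meanSkewness = m, sdSkewness = s,
             flagged = (m - s) > threshold, row.names = NULL)
}
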