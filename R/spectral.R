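#' Combined spectrogram of a drawing trajectory
#'
#' High-pass filters `x(t)` and `y(t)` at 0.5 Hz (zero-phase 501-tap Hann
#' FIR) and computes the short-time Fourier transform of each with a
#' 512-sample Hann window, 5-sample step (0.05 s at 100 samples/s) and 256
#' retained frequency bins, then combines the two as
#' `STFTc(f,t) = |STFTx|^2 + |STFTy|^2`.
#'
#' Power columns use one-sided density scaling (`2 |X|^2 / (fs * sum(w^2))`,
#' DC not doubled) so that integrating a column over frequency approximates
#' the windowed signal power; any fixed convention would do since the tQ
#' statistic downstream is a ratio.
#'
#' @param rec a [drawingRecording()] of at least 512 samples.
#' @param windowLength STFT window in samples.
#' @param step hop size in samples.
#' @return object of class `CombinedSpectrogram`: list with `frequencies`
#'   (Hz, 256 bins from 0 towards Nyquist), `times` (s, window centres) and
#'   `power` (frequencies x times, non-negative).
#' @export
combinedSpectrogram <- function(rec, windowLength = 512L, step = 5L) {
  n <- length(rec$x)
  if (n < windowLength)
    stop("recording too short for the STFT window (", windowLength, " samples)")
  fs <- rec$samplingRate
  hp <- designFir(500L, 0.5, fs, type = "high")
  xs <- zeroPhaseFilter(hp, rec$x)
  ys <- zeroPhaseFilter(hp, rec$y)

  starts <- seq(1L, n - windowLength + 1L, by = step)
  w <- as.numeric(signal::hanning(windowLength))
  idx <- outer(0:(windowLength - 1L), starts, "+")
  nHalf <- windowLength %/% 2L                 # 256 retained bins
  scale <- 1 / (fs * sum(w^2))
  stftPower <- function(sig) {
    segs <- matrix(sig[idx], nrow = windowLength) * w
    X <- mvfft(segs)[1:nHalf, , drop = FALSE]
    p <- Mod(X)^2 * scale
    p[-1L, ] <- 2 * p[-1L, ]
    p
  }
  power <- stftPower(xs) + stftPower(ys)
  structure(list(frequencies = (0:(nHalf - 1L)) * fs / windowLength,
                 times = (starts - 1L + (windowLength - 1L) / 2) / fs,
                 power = power, samplingRate = fs),
            class = "CombinedSpectrogram")
}

#' Per-segment power spectral densities
#'
#' Splits the combined spectrogram into 2-s-long segments advancing by one
#' STFT step (0.05 s) and averages the spectrogram columns within each
#' segment, giving the segment PSD `S_i(f)` on the STFT frequency grid.
#' Segments with incomplete 2-s coverage at the spectrogram edges are
#' dropped.
#'
#' @param sg a [combinedSpectrogram()].
#' @param segmentSeconds segment length in s.
#' @return object of class `SegmentSpectra`: list with `frequencies`,
#'   `segmentTimes` (s, segment centres) and `S` (segments x frequencies).
#' @export
segmentSpectra <- function(sg, segmentSeconds = 2) {
  stepSeconds <- diff(sg$times[1:2])
  segCols <- round(segmentSeconds / stepSeconds)
  nt <- ncol(sg$power)
  if (nt < segCols) stop("spectrogram spans less than one segment")
  nseg <- nt - segCols + 1L
  cs <- cbind(0, t(apply(sg$power, 1L, cumsum)))   # nf x (nt+1)
  S <- t(cs[, (segCols + 1L):(nt + 1L), drop = FALSE] -
           cs[, 1:nseg, drop = FALSE]) / segCols   # nseg x nf
  segTimes <- (sg$times[1:nseg] + sg$times[segCols:nt]) / 2
  structure(list(frequencies = sg$frequencies, segmentTimes = segTimes,
                 S = S), class = "SegmentSpectra")
}

#' Fit the 1/f^alpha spectral background
#'
#' Fits `S_N(f) = b |f|^(-alpha)` to a segment PSD over 2--26 Hz by least
#' absolute residuals in log-log coordinates (robust to the spectral peaks,
#' which are the outliers here). Solved by iteratively reweighted least
#' squares on the linear model `log10 S = log10 b - alpha log10 f` (at most
#' `maxIter` iterations, weight floor `weightFloor`, early exit on
#' convergence). `alpha` is clipped at 0; a flat or rising background then
#' fits with `alpha = 0` and `b` at the L1 optimum (the median of `S` in
#' log10).
#'
#' @param S segment PSD: numeric vector on `frequencies`, or a matrix with
#'   one segment per row (all rows fitted jointly).
#' @param frequencies Hz, matching `S`'s columns.
#' @param fitRange frequency range of the fit, Hz.
#' @param maxIter,weightFloor IRLS controls.
#' @return list with `b` and `alpha` (vectors when `S` is a matrix) and
#'   `floored` (TRUE where non-positive spectral values were epsilon-floored
#'   before taking logs).
#' @export
fitBackground <- function(S, frequencies, fitRange = c(2, 26),
                          maxIter = 50L, weightFloor = 1e-8) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1L)
  sel <- which(frequencies >= fitRange[1] & frequencies <= fitRange[2])
  if (length(sel) < 3L) stop("too few grid frequencies in the fit range")
  xg <- -log10(frequencies[sel])
  Ssel <- S[, sel, drop = FALSE]
  floored <- rowSums(Ssel <= 0) > 0
  Y <- log10(pmax(Ssel, 1e-300))
  W <- matrix(1, nrow(Y), ncol(Y))
  prev <- NULL
  for (it in seq_len(maxIter)) {
    sw <- rowSums(W)
    sx <- as.numeric(W %*% xg)
    sxx <- as.numeric(W %*% xg^2)
    sy <- rowSums(W * Y)
    sxy <- as.numeric((W * Y) %*% xg)
    den <- sw * sxx - sx^2
    slope <- (sw * sxy - sx * sy) / den
    inter <- (sy - slope * sx) / sw
    if (!is.null(prev) &&
        max(abs(slope - prev$slope), abs(inter - prev$inter)) < 1e-12) break
    prev <- list(slope = slope, inter = inter)
    resid <- abs(Y - (inter + outer(slope, xg)))
    W <- 1 / pmax(resid, weightFloor)
  }
  alpha <- prev$slope
  inter <- prev$inter
  neg <- which(alpha < 0)
  if (length(neg)) {   # clip at 0: L1-optimal constant is the median
    alpha[neg] <- 0
    inter[neg] <- apply(Y[neg, , drop = FALSE], 1L, median)
  }
  list(b = 10^inter, alpha = alpha, floored = floored)
}

# fixed residual-spectrum binning: 26 half-open 0.5 Hz bins over 2-15 Hz,
# final edge closed
.tqBinEdges <- seq(2, 15, by = 0.5)
.tqBinCenters <- .tqBinEdges[-length(.tqBinEdges)] + 0.25

#' tQ bin centre frequencies
#'
#' Centres of the 26 fixed 0.5 Hz bins spanning 2--15 Hz used by the tQ
#' statistic: 2.25, 2.75, ..., 14.75 Hz.
#' @return numeric vector of length 26.
#' @export
tqBinCenters <- function() .tqBinCenters

# membership matrix of grid frequencies in the 26 bins
.tqBinMatrix <- function(frequencies) {
  edges <- .tqBinEdges
  nb <- length(edges) - 1L
  M <- matrix(0, length(frequencies), nb)
  for (k in seq_len(nb)) {
    upper <- if (k == nb) frequencies <= edges[k + 1L] else frequencies < edges[k + 1L]
    M[frequencies >= edges[k] & upper, k] <- 1
  }
  M
}

#' Complete one segment with its tQ statistic
#'
#' From a segment PSD and its fitted background: the residual spectrum
#' `S_T(f) = S(f) / (b f^-alpha)` is partitioned into the 26 fixed 0.5 Hz
#' bins over 2--15 Hz and the total residual power per bin gives the bin
#' variances. Sorting them ascending into `W[1..26]`, the statistic is
#' `tQ = W[26] / mean(W[1..23])` — the top bin against the 23 smallest,
#' with ranks 24 and 25 excluded from the background average because they
#' may carry harmonics of the dominant bin. `f_tQ` is the centre frequency
#' of the maximum-variance bin (ties broken toward the lowest frequency).
#'
#' @param S numeric vector: segment PSD on `frequencies`.
#' @param frequencies Hz.
#' @param b,alpha fitted background parameters (from [fitBackground()]).
#' @return list with `binVariances` (26, in frequency order), `W` (sorted
#'   ascending), `tQ`, `fTq` (Hz) and `degenerate` (TRUE when the residual
#'   is all zero, in which case `tQ` is NA).
#' @export
tqFromSegment <- function(S, frequencies, b, alpha) {
  sel <- frequencies >= 2 & frequencies <= 15
  f <- frequencies[sel]
  ST <- S[sel] / (b * f^(-alpha))
  v <- as.numeric(ST %*% .tqBinMatrix(f))
  if (all(v == 0))
    return(list(binVariances = v, W = sort(v), tQ = NA_real_,
                fTq = NA_real_, degenerate = TRUE))
  W <- sort(v)
  list(binVariances = v, W = W, tQ = W[26] / mean(W[1:23]),
       fTq = .tqBinCenters[which.max(v)], degenerate = FALSE)
}

#' Per-segment tQ series of a recording
#'
#' Chains [combinedSpectrogram()], [segmentSpectra()], [fitBackground()] and
#' the binned residual-variance ratio of [tqFromSegment()] for every 2-s
#' segment of the recording.
#'
#' @param rec a [drawingRecording()].
#' @return data.frame with one row per segment: `segment`, `time` (s), `tQ`,
#'   `f_tQ` (Hz), `alpha`, `b` and `degenerate`.
#' @export
tqSeries <- function(rec) {
  sg <- combinedSpectrogram(rec)
  seg <- segmentSpectra(sg)
  bg <- fitBackground(seg$S, seg$frequencies)
  sel <- seg$frequencies >= 2 & seg$frequencies <= 15
  f <- seg$frequencies[sel]
  logSN <- outer(log10(bg$b), rep(1, length(f))) -
    outer(bg$alpha, log10(f))
  ST <- seg$S[, sel, drop = FALSE] / 10^logSN
  V <- ST %*% .tqBinMatrix(f)                      # nseg x 26
  Wsort <- t(apply(V, 1L, sort))
  tQ <- Wsort[, 26] / rowMeans(Wsort[, 1:23, drop = FALSE])
  fTq <- .tqBinCenters[max.col(V, ties.method = "first")]
  degen <- rowSums(V != 0) == 0
  tQ[degen] <- NA_real_
  fTq[degen] <- NA_real_
  data.frame(segment = seq_len(nrow(V)), time = seg$segmentTimes,
             tQ = tQ, f_tQ = fTq, alpha = bg$alpha, b = bg$b,
             degenerate = degen)
}

#' Trajectory power above 3 Hz
#'
#' Welch PSDs of `x(t)` and `y(t)` (1024 frequency bins, 1000-sample Hann
#' window, 80% overlap) are summed into a total PSD and integrated over
#' frequencies above 3 Hz. Returns the band power (mm^2) and its log10 —
#' the `PSDc_var_3Hz` and `PSDc_var_3Hz_log` parameters.
#'
#' @param rec a [drawingRecording()] of at least 1000 samples.
#' @return list with `power` and `log10Power`.
#' @export
psdPowerAbove3Hz <- function(rec) {
  px <- welchPsd(rec$x, rec$samplingRate)
  py <- welchPsd(rec$y, rec$samplingRate)
  total <- px$density + py$density
  df <- px$frequency[2] - px$frequency[1]
  p <- sum(total[px$frequency > 3]) * df
  list(power = p, log10Power = log10(p))
}
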