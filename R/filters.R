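#' FIR filter design by the window method
#'
#' Thin wrapper around [signal::fir1()] with a Hann window. The order must be
#' even for high-pass filters (type-I linear phase); an odd order is
#' incremented with a warning by the underlying routine.
#'
#' @param order filter order (number of taps minus one).
#' @param cutoffHz cutoff frequency in Hz (length 2 for a band-pass).
#' @param samplingRate sampling rate in samples/s.
#' @param type one of `"low"`, `"high"`, `"pass"`.
#' @return numeric vector of `order + 1` filter coefficients.
#' @export
designFir <- function(order, cutoffHz, samplingRate, type = "low") {
  nyquist <- samplingRate / 2
  stopifnot(all(cutoffHz > 0), all(cutoffHz < nyquist))
  as.numeric(signal::fir1(order, cutoffHz / nyquist, type = type,
                          window = signal::hanning(order + 1)))
}

# centred ("same") FFT convolution with an odd-length kernel
convSame <- function(h, x) {
  full <- convolve(x, rev(h), type = "open")
  off <- (length(h) - 1L) %/% 2L
  full[(off + 1L):(off + length(x))]
}

#' Zero-phase FIR filtering
#'
#' Applies a linear-phase FIR filter forward and backward (zero net delay,
#' squared magnitude response). The signal is extended by odd reflection
#' about its endpoints to suppress startup transients, which matters for
#' the very long (2001-tap) low-cutoff filters used on drawing signals.
#'
#' @param h odd-length FIR coefficient vector.
#' @param x signal.
#' @return filtered signal, same length as `x`.
#' @export
zeroPhaseFilter <- function(h, x) {
  n <- length(x)
  L <- length(h)
  if (L %% 2L == 0L) stop("zeroPhaseFilter expects an odd number of taps")
  pad <- min(n - 1L, 3L * L)
  headRef <- 2 * x[1] - x[pad + 1L - seq_len(pad) + 1L]
  tailRef <- 2 * x[n] - x[n - seq_len(pad)]
  xx <- c(headRef, x, tailRef)
  y <- convSame(h, xx)
  y <- rev(convSame(h, rev(y)))
  y[pad + seq_len(n)]
}

#' Welch power spectral density
#'
#' One-sided Welch estimate with a Hann window, mean removal per segment and
#' density scaling (integrating the returned density over frequency recovers
#' the signal's mean power, up to windowing leakage).
#'
#' @param x signal.
#' @param samplingRate samples/s.
#' @param nfft FFT length (zero-padded when longer than `windowLength`).
#' @param windowLength samples per segment.
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `frequency` (Hz, length `nfft/2 + 1`) and `density`
#'   (power per Hz).
#' @export
welchPsd <- function(x, samplingRate, nfft = 1024L, windowLength = 1000L,
                     overlap = 0.8) {
  n <- length(x)
  if (n < windowLength) stop("signal shorter than the Welch window (",
                             windowLength, " samples)")
  step <- max(1L, round(windowLength * (1 - overlap)))
  starts <- seq(1L, n - windowLength + 1L, by = step)
  w <- as.numeric(signal::hanning(windowLength))
  scale <- 1 / (samplingRate * sum(w^2))
  nHalf <- nfft %/% 2L
  acc <- numeric(nHalf + 1L)
  for (s in starts) {
    seg <- x[s:(s + windowLength - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - windowLength)))
    p <- Mod(X[1:(nHalf + 1L)])^2 * scale
    p[2:nHalf] <- 2 * p[2:nHalf]  # fold negative frequencies (not DC/Nyquist)
    acc <- acc + p
  }
  list(frequency = (0:nHalf) * samplingRate / nfft,
       density = acc / length(starts))
}
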