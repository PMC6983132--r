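#' Coarse-grain a signal
#'
#' Block-averaging step of multiscale entropy: the coarse-grained series at
#' scale `tau` has length `floor(N/tau)` and each sample is the mean of its
#' non-overlapping block of `tau` original samples.
#'
#' @param x signal.
#' @param tau integer scale (>= 1); `tau = 1` is the identity.
#' @return coarse-grained signal.
#' @export
coarseGrain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1")
  if (tau == 1L) return(x)
  n <- (length(x) %/% tau) * tau
  if (n < tau) stop("signal shorter than one block")
  colMeans(matrix(x[seq_len(n)], nrow = tau))
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` counts ordered distinct pairs of `m`-sample
#' templates whose Chebyshev distance is strictly below `rAbs` and `A`
#' counts the same pairs still matching after extension to `m + 1` samples;
#' self-matches are excluded and both counts run over the templates that can
#' be extended.
#'
#' When no template pair matches at length `m + 1` (`A = 0`) the entropy is
#' `+Inf` and the result is flagged (`attr(., "flag") == "no_m1_matches"`);
#' with no matches at length `m` at all (`B = 0`) the value is undefined and
#' returned as `NaN` with flag `"no_m_matches"`. Downstream feature assembly
#' substitutes flagged sentinels (see [assembleMatrix()]).
#'
#' @param x signal of length >= `m + 2`.
#' @param m embedding (template) length.
#' @param rAbs absolute similarity threshold, in the units of `x`.
#' @return entropy in nats, with attributes `A` and `B` (the pair counts)
#'   and optionally `flag`.
#' @export
sampleEntropy <- function(x, m = 2L, rAbs) {
  if (length(x) < m + 2L) stop("signal too short for SampEn (need m + 2 samples)")
  if (rAbs <= 0) stop("rAbs must be positive")
  counts <- sampen_counts_cpp(as.numeric(x), as.integer(m), rAbs)
  A <- counts[1]; B <- counts[2]
  if (B == 0) {
    out <- NaN
    attr(out, "flag") <- "no_m_matches"
  } else if (A == 0) {
    out <- Inf
    attr(out, "flag") <- "no_m1_matches"
  } else {
    out <- -log(A / B)
  }
  attr(out, "A") <- A
  attr(out, "B") <- B
  out
}

#' Multiscale entropy
#'
#' Sample entropy of the coarse-grained signal at scale `tau`, with the
#' similarity threshold expressed as `rFactor` times the standard deviation
#' of the *original* (pre-coarse-graining) series, the standard multiscale
#' convention that keeps scales comparable. The 0.15 default is a
#' calibration knob: no canonical value exists for tablet velocity signals.
#'
#' @param x signal.
#' @param m template length.
#' @param rFactor threshold as a fraction of `sd(x)`.
#' @param tau integer scale.
#' @return entropy in nats (see [sampleEntropy()] for the flagged sentinels).
#' @export
multiscaleEntropy <- function(x, m = 2L, rFactor = 0.15, tau = 1L) {
  s <- sd(x)
  if (s == 0) {  # constant signal: all templates match at every length
    out <- 0
    attr(out, "A") <- attr(out, "B") <- NA_real_
    return(out)
  }
  sampleEntropy(coarseGrain(x, tau), m = m, rAbs = rFactor * s)
}
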