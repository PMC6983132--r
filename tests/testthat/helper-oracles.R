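# Independent oracle implementations used across the suite. These are kept
# deliberately naive (full distance matrices, per-bin loops) and share no
# code with the package internals they check.

# SampEn template counts via full Chebyshev distance matrices; ordered
# distinct pairs, strict < r, counted over the templates that can be
# extended to length m + 1.
oracleSampenCounts <- function(x, m, r) {
  n <- length(x)
  Nt <- n - m
  cheb <- function(len) {
    D <- matrix(0, Nt, Nt)
    for (j in 0:(len - 1))
      D <- pmax(D, abs(outer(x[(1:Nt) + j], x[(1:Nt) + j], "-")))
    D
  }
  Dm <- cheb(m)
  Dm1 <- pmax(Dm, abs(outer(x[(1:Nt) + m], x[(1:Nt) + m], "-")))
  diag(Dm) <- Inf
  diag(Dm1) <- Inf
  c(A = sum(Dm1 < r), B = sum(Dm < r))
}

# Unoptimized recomputation of the binned residual-variance ratio from a
# segment PSD and its fitted background.
oracleTq <- function(S, f, b, alpha) {
  edges <- seq(2, 15, by = 0.5)
  v <- numeric(26)
  for (k in 1:26) {
    inBin <- if (k < 26) f >= edges[k] & f < edges[k + 1]
             else f >= edges[k] & f <= edges[k + 1]
    v[k] <- sum(S[inBin] / (b * f[inBin]^(-alpha)))
  }
  W <- sort(v)
  list(tQ = W[26] / mean(W[1:23]),
       fTq = (edges[-27] + 0.25)[which.max(v)],
       binVariances = v)
}

# A minimal valid recording from explicit series (defaults give a clean
# constant-speed circle, 65 mm radius centred at (100, 100)).
makeCircleRecording <- function(duration = 20, samplingRate = 100,
                                radius = 65, revFreq = 0.35,
                                center = c(100, 100), pressure = NULL,
                                xFun = NULL, yFun = NULL) {
  t <- (seq_len(duration * samplingRate) - 1) / samplingRate
  x <- if (is.null(xFun)) center[1] + radius * cos(2 * pi * revFreq * t)
       else xFun(t)
  y <- if (is.null(yFun)) center[2] + radius * sin(2 * pi * revFreq * t)
       else yFun(t)
  drawingRecording(x = x, y = y, pressure = pressure,
                   samplingRate = samplingRate,
                   templateDiameter = 2 * radius, templateCenter = center)
}
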