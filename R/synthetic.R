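#' Specification of a synthetic circle drawing
#'
#' Parameters of the generator that emulates the tablet measurement: a slow
#' circular trace around the template with an intermittent sinusoidal tremor
#' component, white positional jitter, clipped-Gaussian pen pressure and
#' optional off-template artifacts.
#'
#' Defaults mirror the measurement conditions: 100 s at 100 samples/s on a
#' 130 mm template (65 mm radius), a "moderate" drawing speed of 0.35
#' revolutions/s, and a tremor in the 4--9 Hz kinetic-tremor band. The
#' tremor direction rotates slowly (50 s period, much longer than one
#' revolution) so both coordinates carry tremor power, and bursts follow a
#' two-state Markov gate with 3 s mean burst length (the symptom is highly
#' intermittent).
#'
#' @param duration recording length in s.
#' @param samplingRate samples/s.
#' @param circleRadius template radius in mm.
#' @param revolutionFreq drawing speed in revolutions/s.
#' @param tremorFreq tremor frequency in Hz; must lie in `[1, 12]`, below
#'   the tablet's 13 Hz cut-off.
#' @param tremorAmp tremor amplitude in mm (>= 0).
#' @param intermittency fraction of time the tremor is active (0--1).
#' @param burstMean mean tremor burst length in s.
#' @param jitterSd white positional noise SD in mm.
#' @param pressureMean,pressureSd pen pressure mean and SD in device units.
#' @param artifactProb probability of one off-template excursion artifact.
#' @param seed integer RNG seed; the recording is deterministic given the
#'   spec.
#' @return object of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(duration = 100, samplingRate = 100,
                          circleRadius = 65, revolutionFreq = 0.35,
                          tremorFreq = 5.3, tremorAmp = 1,
                          intermittency = 0.5, burstMean = 3,
                          jitterSd = 0.2, pressureMean = 500,
                          pressureSd = 30, artifactProb = 0, seed = 1L) {
  stopifnot(duration > 0, samplingRate > 0, circleRadius > 0,
            revolutionFreq > 0, tremorFreq >= 1, tremorFreq <= 12,
            tremorAmp >= 0, intermittency >= 0, intermittency <= 1,
            burstMean > 0, jitterSd >= 0, pressureSd >= 0,
            artifactProb >= 0, artifactProb <= 1)
  structure(list(duration = duration, samplingRate = samplingRate,
                 circleRadius = circleRadius,
                 revolutionFreq = revolutionFreq, tremorFreq = tremorFreq,
                 tremorAmp = tremorAmp, intermittency = intermittency,
                 burstMean = burstMean, jitterSd = jitterSd,
                 pressureMean = pressureMean, pressureSd = pressureSd,
                 artifactProb = artifactProb, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# two-state Markov on/off gate with stationary on-fraction p and mean
# on-duration burstMean (s)
markovGate <- function(n, p, burstMean, samplingRate) {
  if (p <= 0) return(numeric(n))
  if (p >= 1) return(rep(1, n))
  dt <- 1 / samplingRate
  pOffGivenOn <- min(1, dt / burstMean)
  meanOff <- burstMean * (1 - p) / p
  pOnGivenOff <- min(1, dt / meanOff)
  state <- as.numeric(runif(1) < p)
  g <- numeric(n)
  u <- runif(n)
  for (i in seq_len(n)) {
    g[i] <- state
    state <- if (state == 1) {
      if (u[i] < pOffGivenOn) 0 else 1
    } else {
      if (u[i] < pOnGivenOff) 1 else 0
    }
  }
  g
}

#' Simulate a circle drawing with intermittent tremor
#'
#' Generates `x(t), y(t)` as a circle of `circleRadius` traced at
#' `revolutionFreq` around the template centre, plus a tremor component
#' `tremorAmp * sin(2 pi tremorFreq t + phase)` applied along a slowly
#' rotating direction and gated by a burst process, plus Gaussian jitter.
#' Pressure is a clipped Gaussian. With `artifactProb`, a 2-s window is
#' replaced by a linear dash to a point outside the template and back.
#'
#' @param spec a [syntheticSpec()].
#' @return a [drawingRecording()]; deterministic given `spec` (including its
#'   seed).
#' @export
simulateDrawing <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  fs <- spec$samplingRate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1L) / fs
  center <- c(100, 100)  # template centre on the tablet, mm

  phase0 <- runif(1, 0, 2 * pi)
  theta <- 2 * pi * spec$revolutionFreq * t + phase0
  x <- center[1] + spec$circleRadius * cos(theta)
  y <- center[2] + spec$circleRadius * sin(theta)

  # tremor along a slowly rotating direction (50 s period >> revolution)
  dirFreq <- 0.02
  psi <- 2 * pi * dirFreq * t + runif(1, 0, 2 * pi)
  gate <- markovGate(n, spec$intermittency, spec$burstMean, fs)
  trem <- spec$tremorAmp * gate *
    sin(2 * pi * spec$tremorFreq * t + runif(1, 0, 2 * pi))
  x <- x + trem * cos(psi)
  y <- y + trem * sin(psi)

  if (spec$jitterSd > 0) {
    x <- x + rnorm(n, 0, spec$jitterSd)
    y <- y + rnorm(n, 0, spec$jitterSd)
  }

  if (spec$artifactProb > 0 && runif(1) < spec$artifactProb) {
    span <- round(2 * fs)
    start <- sample.int(max(1L, n - span), 1L)
    idx <- start:(start + span - 1L)
    away <- runif(1, 0, 2 * pi)
    target <- center + 1.8 * spec$circleRadius * c(cos(away), sin(away))
    half <- length(idx) %/% 2L
    ramp <- c(seq(0, 1, length.out = half),
              seq(1, 0, length.out = length(idx) - half))
    x[idx] <- x[idx[1]] + (target[1] - x[idx[1]]) * ramp
    y[idx] <- y[idx[1]] + (target[2] - y[idx[1]]) * ramp
  }

  pressure <- pmin(1023, pmax(0, rnorm(n, spec$pressureMean, spec$pressureSd)))

  drawingRecording(x = x, y = y, pressure = pressure, samplingRate = fs,
                   hand = "unknown",
                   templateDiameter = 2 * spec$circleRadius,
                   templateCenter = center,
                   meta = list(source = "synthetic",
                               tremor_amp = spec$tremorAmp,
                               tremor_freq = spec$tremorFreq))
}

#' Amplitude grid spanning the 0--10 score range
#'
#' Fixed 11-point grid: 0 mm for score 0, then a geometric progression from
#' 0.1 mm to 8 mm for scores 1..10. This gives a strictly monotone synthetic
#' ground truth linking tremor amplitude to the integer visual score; it is
#' a stand-in calibration, not a claim about clinical scoring.
#'
#' @return numeric vector of 11 amplitudes (mm), names `0..10`.
#' @export
scoreAmplitudeGrid <- function() {
  amps <- c(0, 0.1 * (8 / 0.1)^((0:9) / 9))
  names(amps) <- 0:10
  amps
}

#' Map a tremor amplitude to its synthetic score
#'
#' Index (0-based) of the amplitude in [scoreAmplitudeGrid()], by nearest
#' grid point; monotone in amplitude.
#'
#' @param amplitude tremor amplitude(s) in mm.
#' @return integer score(s) in 0..10.
#' @export
defaultScoreMap <- function(amplitude) {
  grid <- scoreAmplitudeGrid()
  vapply(amplitude, function(a) which.min(abs(grid - a)) - 1L, integer(1))
}

#' Simulate a rated dataset of circle drawings
#'
#' Tremor amplitudes cycle through [scoreAmplitudeGrid()] (so `n = 11`
#' yields exactly one recording per score 0..10) and each recording is
#' scored with `scoreMap`. Tremor frequency is drawn per recording uniformly
#' from the 4--9 Hz kinetic-tremor band; the UPDRS.21 rating is a coarsened
#' copy of the 0--10 score (`round(0.4 * score)`). Reproducible from `seed`.
#'
#' @param n number of recordings.
#' @param seed integer master seed.
#' @param baseSpec template [syntheticSpec()]; amplitude, frequency and seed
#'   fields are overridden per recording.
#' @param scoreMap monotone map from amplitude (mm) to integer score.
#' @return list with `recordings` (list of [drawingRecording()]), `ratings`
#'   (data.frame `recording_id`, `tremor_score`, `updrs21`) and `amplitudes`.
#' @export
simulateDataset <- function(n, seed = 1L, baseSpec = syntheticSpec(),
                            scoreMap = defaultScoreMap) {
  stopifnot(n >= 1)
  grid <- scoreAmplitudeGrid()
  if (!length(grid)) stop("empty amplitude grid")
  amps <- rep(grid, length.out = n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  freqs <- runif(n, 4, 9)
  recSeeds <- (as.integer(seed) + 7919L * seq_len(n)) %% 2147483647L
  recordings <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- baseSpec
    spec$tremorAmp <- unname(amps[i])
    spec$tremorFreq <- freqs[i]
    spec$seed <- recSeeds[i]
    recordings[[i]] <- simulateDrawing(spec)
  }
  scores <- scoreMap(unname(amps))
  ratings <- data.frame(
    recording_id = sprintf("rec%04d", seq_len(n)),
    tremor_score = as.integer(scores),
    updrs21 = as.integer(round(0.4 * scores)))
  list(recordings = recordings, ratings = ratings, amplitudes = unname(amps))
}
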