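#' Drawing recording
#'
#' Container for a circle-drawing recording from a digitizing tablet:
#' uniformly sampled pen position (mm) and pen pressure (device units,
#' 0--1023), plus template metadata. The nominal device samples at
#' 100 samples/s and the drawing template is a 130 mm circle.
#'
#' @param x,y pen position in mm.
#' @param pressure pen pressure in device units (0--1023). `NULL` is allowed
#'   for position-only data and is filled with a constant 512; pressure-based
#'   features then carry a quality flag (see [validateRecording()]).
#' @param time optional time vector in s; derived from `samplingRate`
#'   (starting at 0) when `NULL`.
#' @param samplingRate samples/s.
#' @param hand `"left"`, `"right"` or `"unknown"`.
#' @param templateDiameter template circle diameter in mm.
#' @param templateCenter template centre `(x, y)` in mm, tablet lower-left
#'   origin.
#' @param meta named list of free-form metadata (subject id, session id...).
#' @return an object of class `DrawingRecording`. The constructor does not
#'   reject invalid physical content; use [validateRecording()] to obtain a
#'   report of violations.
#' @seealso [readRecording()], [writeRecording()], [simulateDrawing()]
#' @export
drawingRecording <- function(x, y, pressure = NULL, time = NULL,
                             samplingRate = 100, hand = "unknown",
                             templateDiameter = 130,
                             templateCenter = c(0, 0), meta = list()) {
  n <- length(x)
  if (is.null(time)) time <- (seq_len(n) - 1L) / samplingRate
  pressureImputed <- is.null(pressure)
  if (pressureImputed) pressure <- rep(512, n)
  hand <- match.arg(hand, c("left", "right", "unknown"))
  structure(list(time = as.numeric(time), x = as.numeric(x),
                 y = as.numeric(y), pressure = as.numeric(pressure),
                 samplingRate = samplingRate, hand = hand,
                 templateDiameter = templateDiameter,
                 templateCenter = as.numeric(templateCenter),
                 pressureImputed = pressureImputed, meta = meta),
            class = "DrawingRecording")
}

#' @export
print.DrawingRecording <- function(x, ...) {
  cat(sprintf("DrawingRecording: %d samples at %g samples/s (%.1f s), hand %s\n",
              length(x$x), x$samplingRate, length(x$x) / x$samplingRate,
              x$hand))
  cat(sprintf("  template: %g mm diameter at (%g, %g) mm\n",
              x$templateDiameter, x$templateCenter[1], x$templateCenter[2]))
  v <- validateRecording(x)
  if (length(v)) cat("  violations:", paste(v, collapse = "; "), "\n")
  invisible(x)
}

#' Validate a drawing recording
#'
#' Checks the physical-plausibility invariants: all series equal length,
#' duration at least 10 s (the minimum for the downstream 2-s spectral
#' segments and entropy scales), a strictly increasing uniform time grid
#' (step `1/samplingRate` within 1e-9 relative tolerance), and pressure
#' within `[0, 1023]`. Reports rather than throws.
#'
#' @param rec a [drawingRecording()].
#' @return character vector of violations; empty when the recording is valid.
#' @export
validateRecording <- function(rec) {
  out <- character()
  n <- length(rec$x)
  if (length(rec$y) != n || length(rec$pressure) != n ||
      length(rec$time) != n)
    out <- c(out, "series lengths differ")
  if (n < rec$samplingRate * 10)
    out <- c(out, "duration below minimum (10 s)")
  if (n >= 2) {
    dt <- diff(rec$time)
    step <- 1 / rec$samplingRate
    if (any(dt <= 0) || max(abs(dt - step)) > 1e-9 * max(step, 1))
      out <- c(out, "non-uniform time grid")
  }
  if (any(rec$pressure < 0 | rec$pressure > 1023))
    out <- c(out, "pressure out of range")
  if (isTRUE(rec$pressureImputed))
    out <- c(out, "pressure imputed (position-only source)")
  out
}

# header keys with dedicated fields; anything else round-trips through meta
.recKnownKeys <- c("format", "sampling_rate", "units", "hand",
                   "template_diameter", "template_center", "precision")

#' Write a drawing recording to a plain-text file
#'
#' Canonical serialization: UTF-8 text, `# key: value` header lines
#' (sampling rate, units, hand, template geometry, decimal precision and any
#' metadata), followed by TAB-separated `t x y p` rows formatted at the
#' declared precision. Writing the result of [readRecording()] reproduces
#' the canonicalized file byte for byte.
#'
#' @param rec a [drawingRecording()].
#' @param path output file path.
#' @param precision decimal places for all four columns.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, precision = 4L) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(...) writeLines(sprintf(...), con, sep = "\n")
  put("# format: tremorkit-recording-1")
  put("# sampling_rate: %.10g", rec$samplingRate)
  put("# units: mm")
  put("# hand: %s", rec$hand)
  put("# template_diameter: %.10g", rec$templateDiameter)
  put("# template_center: %.10g %.10g", rec$templateCenter[1],
      rec$templateCenter[2])
  put("# precision: %d", precision)
  for (key in sort(names(rec$meta)))
    put("# %s: %s", key, as.character(rec$meta[[key]]))
  fmt <- sprintf("%%.%df", precision)
  rows <- paste(sprintf(fmt, rec$time), sprintf(fmt, rec$x),
                sprintf(fmt, rec$y), sprintf(fmt, rec$pressure),
                sep = "\t")
  writeLines(rows, con, sep = "\n")
  invisible(path)
}

#' Read a drawing recording from a plain-text file
#'
#' Parses the format written by [writeRecording()]. The time column is
#' checked for uniform sampling (a deviation beyond the declared precision's
#' quantization error is an error naming the offending row) and then
#' replaced by the exact grid `t[1] + (0:(n-1))/sampling_rate`, so the
#' in-memory recording satisfies the 1e-9 uniformity invariant regardless
#' of the file's decimal precision.
#'
#' @param path file path.
#' @return a validated [drawingRecording()].
#' @export
readRecording <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  isHeader <- grepl("^#", lines)
  headerEnd <- if (any(!isHeader)) which(!isHeader)[1] - 1L else length(lines)
  header <- lines[seq_len(headerEnd)]
  kv <- regmatches(header, regexec("^#\\s*([^:]+):\\s*(.*)$", header))
  keys <- vapply(kv, function(m) if (length(m) == 3) trimws(m[2]) else NA_character_, "")
  vals <- vapply(kv, function(m) if (length(m) == 3) trimws(m[3]) else NA_character_, "")
  getKey <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) default else vals[i]
  }
  samplingRate <- as.numeric(getKey("sampling_rate", NA))
  if (is.na(samplingRate)) stop("recording header lacks sampling_rate")
  precision <- as.integer(getKey("precision", "4"))
  hand <- getKey("hand", "unknown")
  templateDiameter <- as.numeric(getKey("template_diameter", "130"))
  center <- as.numeric(strsplit(getKey("template_center", "0 0"), "\\s+")[[1]])
  units <- getKey("units", "mm")
  metaKeys <- setdiff(keys[!is.na(keys)], .recKnownKeys)
  meta <- as.list(setNames(vals[match(metaKeys, keys)], metaKeys))

  body <- lines[!isHeader & nzchar(lines)]
  if (!length(body)) stop("recording file has no data rows")
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 4))
    stop("missing columns at row ", which(ncols != 4)[1],
         " (expected 4 TAB-separated columns t, x, y, p)")
  m <- matrix(as.numeric(unlist(fields)), ncol = 4, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric value at row ", which(rowSums(is.na(m)) > 0)[1])
  t <- m[, 1]; x <- m[, 2]; y <- m[, 3]; p <- m[, 4]
  if (units == "counts") {  # device counts at 0.01 mm resolution
    x <- x * 0.01; y <- y * 0.01
  }
  step <- 1 / samplingRate
  if (length(t) >= 2) {
    dev <- abs(diff(t) - step)
    tol <- max(1.5 * 10^(-precision), 1e-9 * step)
    if (any(dev > tol))
      stop("non-uniform sampling at row ", which(dev > tol)[1] + 1L)
  }
  bad <- which(p < 0 | p > 1023)
  if (length(bad)) stop("pressure out of range at row ", bad[1])
  time <- t[1] + (seq_along(t) - 1L) / samplingRate
  drawingRecording(x = x, y = y, pressure = p, time = time,
                   samplingRate = samplingRate, hand = hand,
                   templateDiameter = templateDiameter,
                   templateCenter = center, meta = meta)
}

#' Tremor rating
#'
#' Integer visual rating of kinetic tremor: `tremorScore` on the 0--10 scale
#' and, optionally, UPDRS item 21 on the 0--4 scale.
#'
#' @param tremorScore integer in 0..10.
#' @param updrs21 optional integer in 0..4.
#' @return object of class `TremorRating`.
#' @export
tremorRating <- function(tremorScore, updrs21 = NA_integer_) {
  tremorScore <- as.integer(tremorScore)
  updrs21 <- as.integer(updrs21)
  stopifnot(tremorScore >= 0, tremorScore <= 10)
  if (!is.na(updrs21)) stopifnot(updrs21 >= 0, updrs21 <= 4)
  structure(list(tremorScore = tremorScore, updrs21 = updrs21),
            class = "TremorRating")
}

#' Read/write a ratings table
#'
#' TAB-separated table with columns `recording_id`, `tremor_score` and
#' `updrs21` (empty cell for an absent UPDRS.21 rating).
#'
#' @param path file path.
#' @return `readRatings` returns a data.frame with the three columns.
#' @export
readRatings <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer"),
                   na.strings = "")
  names(df) <- c("recording_id", "tremor_score", "updrs21")
  df
}

#' @rdname readRatings
#' @param ratings data.frame with columns `recording_id`, `tremor_score`,
#'   `updrs21`.
#' @export
writeRatings <- function(ratings, path) {
  write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
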