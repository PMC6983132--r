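#' Pipeline configuration
#'
#' Bundles every knob of the simulate -> features -> train -> predict ->
#' evaluate workflow. A single master seed is fanned out deterministically
#' to the stages (dataset simulation, splitting, model fitting, ensemble
#' initialization), so a rerun with the same config is reproducible
#' end-to-end.
#'
#' The default desk-scale configuration simulates 150 recordings and uses a
#' reduced ensemble grid (N = 50, one repetition per hyperparameter
#' combination, 18 members); the full 216-member grid is
#' [ensembleGrid()]'s default.
#'
#' @param n number of simulated recordings.
#' @param spec base [syntheticSpec()] of the simulated drawings.
#' @param grid [ensembleGrid()] for the reservoir ensembles.
#' @param lambdaChoice `"min"` or `"1se"`.
#' @param scale `"tremor_score"` (bounds 0--10) or `"updrs21"` (0--4).
#' @param trainFraction training share of the stratified split.
#' @param repetitions independent ensemble re-initializations for the
#'   variability experiment.
#' @param seed integer master seed.
#' @return object of class `PipelineConfig`.
#' @export
pipelineConfig <- function(n = 150L, spec = syntheticSpec(),
                           grid = ensembleGrid(N = 50L, nRep = 1L),
                           lambdaChoice = "min", scale = "tremor_score",
                           trainFraction = 0.6, repetitions = 1L,
                           seed = 1L) {
  scale <- match.arg(scale, c("tremor_score", "updrs21"))
  structure(list(n = as.integer(n), spec = spec, grid = grid,
                 lambdaChoice = lambdaChoice, scale = scale,
                 trainFraction = trainFraction,
                 repetitions = as.integer(repetitions),
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipelineConfig()] arguments; `spec` and `grid`
#' are nested maps of [syntheticSpec()] and [ensembleGrid()] arguments.
#'
#' @param path YAML file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 parses bare n/N/y keys as booleans; map them back
  fixKey <- function(l, key) {
    names(l)[names(l) %in% c("FALSE", "TRUE")] <- key
    l
  }
  cfg <- fixKey(cfg, "n")
  args <- cfg[setdiff(names(cfg), c("spec", "grid"))]
  if (!is.null(cfg$spec)) args$spec <- do.call(syntheticSpec, cfg$spec)
  if (!is.null(cfg$grid))
    args$grid <- do.call(ensembleGrid, fixKey(cfg$grid, "N"))
  do.call(pipelineConfig, args)
}

# deterministic per-stage seed fan-out from the master seed
stageSeed <- function(master, stage, index = 0L) {
  stages <- c(simulate = 1L, split = 2L, ts_model = 3L, esn_ensemble = 4L,
              esn_ts_ensemble = 5L)
  h <- stages[[stage]]
  (as.integer(master) + 1000003L * h + 7907L * as.integer(index)) %% 2147483647L
}

#' Run the full scoring pipeline on synthetic data
#'
#' Embodies the training-and-testing workflow: simulate a rated dataset,
#' extract the 23 time-series parameters once, split with stratified
#' sampling, fit the time-series score model, then build `repetitions`
#' independently re-initialized reservoir ensembles (`M_ESN` and
#' `M_ESN+TS`), reusing the signal-based parameters across members, and
#' evaluate every model on the held-out test set with Pearson's r.
#'
#' @param cfg a [pipelineConfig()].
#' @param outDir optional directory; when given, the features table,
#'   ratings table, per-model predictions and a JSON report are written
#'   there and listed (with checksums) in the report manifest.
#' @param verbose print one structured line per stage.
#' @return a run report: list with per-model `r` (and CIs), ensemble
#'   variability summaries, parameter-inclusion tables and the file
#'   `manifest`.
#' @export
runPipeline <- function(cfg, outDir = NULL, verbose = TRUE) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  t0 <- Sys.time()
  say <- function(stage, ...) if (verbose)
    cat(sprintf("[%s] %s %s\n", format(Sys.time(), "%H:%M:%S"), stage,
                sprintf(...)))

  say("simulate", "n=%d seed=%d", cfg$n, stageSeed(cfg$seed, "simulate"))
  ds <- simulateDataset(cfg$n, seed = stageSeed(cfg$seed, "simulate"),
                        baseSpec = cfg$spec)
  y <- if (cfg$scale == "tremor_score") ds$ratings$tremor_score else
    ds$ratings$updrs21
  bounds <- if (cfg$scale == "tremor_score") c(0, 10) else c(0, 4)

  say("features", "extracting %d x 23 time-series parameters", cfg$n)
  fv <- lapply(ds$recordings, extractFeatures)
  DTS <- assembleMatrix(tsFeatures = fv, ids = ds$ratings$recording_id)

  split <- stratifiedSplit(y, cfg$trainFraction,
                           seed = stageSeed(cfg$seed, "split"))
  say("split", "train=%d test=%d", length(split$train), length(split$test))

  mTs <- fitLasso(DTS[split$train, , drop = FALSE], y[split$train],
                  lambdaChoice = cfg$lambdaChoice, scaleBounds = bounds,
                  seed = stageSeed(cfg$seed, "ts_model"))
  predTs <- predict(mTs, DTS[split$test, , drop = FALSE])
  evalTs <- evaluatePredictions(predTs, y[split$test])
  say("ts_model", "r=%.3f", evalTs$r)

  say("preprocess", "reservoir inputs for %d recordings", cfg$n)
  pp <- lapply(ds$recordings, preprocessInput)

  esnRuns <- list()
  esnTsRuns <- list()
  for (rep in seq_len(cfg$repetitions)) {
    eEsn <- buildEnsemble(pp, y, split, grid = cfg$grid, kind = "esn",
                          lambdaChoice = cfg$lambdaChoice,
                          scaleBounds = bounds,
                          seed = stageSeed(cfg$seed, "esn_ensemble", rep))
    eBoth <- buildEnsemble(pp, y, split, grid = cfg$grid, kind = "esn_ts",
                           DTS = DTS, lambdaChoice = cfg$lambdaChoice,
                           scaleBounds = bounds,
                           seed = stageSeed(cfg$seed, "esn_ts_ensemble", rep))
    esnRuns[[rep]] <- eEsn
    esnTsRuns[[rep]] <- eBoth
    say("ensembles", "rep %d: r_ESN=%.3f r_ESN+TS=%.3f", rep,
        evaluatePredictions(eEsn$prediction, y[split$test])$r,
        evaluatePredictions(eBoth$prediction, y[split$test])$r)
  }
  rEsn <- vapply(esnRuns, function(e)
    evaluatePredictions(e$prediction, y[split$test])$r, 0)
  rBoth <- vapply(esnTsRuns, function(e)
    evaluatePredictions(e$prediction, y[split$test])$r, 0)

  report <- list(
    config = list(n = cfg$n, scale = cfg$scale,
                  lambdaChoice = cfg$lambdaChoice, seed = cfg$seed,
                  members = nrow(cfg$grid), repetitions = cfg$repetitions),
    m_ts = list(r = evalTs$r, ci = evalTs$ci,
                inclusion = parameterInclusion(mTs)),
    m_esn_ensemble = list(r = rEsn, min = min(rEsn), median = median(rEsn),
                          max = max(rEsn),
                          inclusion = parameterInclusion(esnRuns[[1]])),
    m_esn_ts_ensemble = list(r = rBoth, min = min(rBoth),
                             median = median(rBoth), max = max(rBoth),
                             inclusion = parameterInclusion(esnTsRuns[[1]])),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    manifest = data.frame(file = character(), md5 = character()))

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    featPath <- file.path(outDir, "features.tsv")
    write.table(cbind(recording_id = rownames(DTS), as.data.frame(DTS)),
                featPath, sep = "\t", quote = FALSE, row.names = FALSE)
    ratPath <- file.path(outDir, "ratings.tsv")
    writeRatings(ds$ratings, ratPath)
    predPath <- file.path(outDir, "predictions.tsv")
    write.table(data.frame(recording_id = ds$ratings$recording_id[split$test],
                           target = y[split$test], m_ts = predTs,
                           m_esn = esnRuns[[1]]$prediction,
                           m_esn_ts = esnTsRuns[[1]]$prediction),
                predPath, sep = "\t", quote = FALSE, row.names = FALSE)
    reportPath <- file.path(outDir, "report.json")
    files <- c(featPath, ratPath, predPath)
    report$manifest <- data.frame(file = basename(files),
                                  md5 = unname(tools::md5sum(files)))
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    report$manifest <- rbind(report$manifest,
                             data.frame(file = basename(reportPath),
                                        md5 = unname(tools::md5sum(reportPath))))
  }
  report
}
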