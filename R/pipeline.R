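#' Default pipeline configuration
#'
#' Flat key/value configuration driving [runPipeline]. Defaults reproduce
#' the published analysis design at demonstration scale: a 32 x 32 km
#' synthetic scene, 60 presence cells, the 250--400 mm / 800 m screening
#' rule, BRT settings (complexity 4, learning rate 0.005, bag fraction 0.75,
#' step size 10, 10 folds), a 10-iteration ensemble (the full design uses
#' 200), RC threshold 2%, and 4 output classes. All values can be overridden
#' via a config file ([readPipelineConfig]) or by editing the returned list.
#'
#' @param output_dir output directory.
#' @param seed master seed.
#' @return named list of settings.
#' @export
defaultPipelineConfig <- function(output_dir = tempfile("hqrun"), seed = 1) {
  list(
    output_dir = output_dir, seed = seed,
    # scene
    grid_ncols = 32, grid_nrows = 32, n_occurrences = 200, n_presence = 60,
    n_samples = 50, target_r2 = 0.35,
    # optional external inputs (paths); when set, simulation is skipped
    stack_manifest = "", occurrences = "", samples = "",
    # screening
    precip_layer = "bio4", elev_layer = "elev",
    precip_low = 250, precip_high = 400, elev_min = 800,
    # BRT
    tree_complexity = 4, learning_rate = 0.005, bag_fraction = 0.75,
    step_size = 10, n_folds = 10, max_trees = 500, min_obs = 10, patience = 5,
    # ensemble / selection / classification
    n_iterations = 10, rc_threshold = 2.0, classes = 4, combine = "product",
    jenks_subsample = 10000
  )
}

#' Read or write a pipeline configuration file
#'
#' INI-style flat `key = value` text; `#` starts a comment. Unknown keys are
#' an error; missing keys take their defaults.
#'
#' @param path config file path.
#' @param base defaults to merge into (see [defaultPipelineConfig]).
#' @return named list of settings.
#' @export
readPipelineConfig <- function(path, base = defaultPipelineConfig()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop("malformed config line: '", ln, "'")
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    if (!key %in% names(base)) stop("unknown config key: '", key, "'")
    base[[key]] <- if (is.numeric(base[[key]]))
      as.numeric(val) else val
  }
  base
}

#' @rdname readPipelineConfig
#' @param config configuration list to write.
#' @export
writePipelineConfig <- function(config, path) {
  writeLines(paste(names(config), unlist(config), sep = " = "), path)
  invisible(path)
}

#' Run the full suitability/quality pipeline
#'
#' Orchestrates all stages in order, writing every intermediate product to
#' the output directory so any stage can be re-run in isolation:
#' \enumerate{
#'   \item simulate: synthetic stack (written as `.asc` + manifest), truth
#'     suitability, occurrence records, compound sample table -- skipped for
#'     any input supplied externally via the config paths;
#'   \item grid: occurrence records (read back from disk) snapped to unique
#'     presence cells;
#'   \item ensemble: background-resampled BRT ensemble; mean/SD suitability
#'     rasters, RC table, per-iteration AUC;
#'   \item quality: main-factor selection, stepwise content regressions on
#'     the continuous main factors, per-compound content rasters and their
#'     min-max-normalized mean as the combined quality layer;
#'   \item classify: overlay of quality on mean suitability, Jenks
#'     four-class map with JSON sidecar.
#' }
#' Identical config + seed give identical outputs (timings aside).
#'
#' @param config list from [defaultPipelineConfig] or [readPipelineConfig].
#' @return a run report (list, class `"RunReport"`): stage timings and
#'   counts, AUC summary, RC table, selected main factors, fitted equations,
#'   break values and accumulated warnings. Also written to
#'   `report.json` in the output directory.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(out, "run.log")
  report <- list(config = config, stages = list(), warnings = character())
  seed <- config$seed
  noteWarn <- function(w) report$warnings <<- c(report$warnings, w)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    logMsg("stage ", name, " started", file = logFile)
    res <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)),
      message = function(m) {
        txt <- conditionMessage(m)
        if (grepl("\\[WARN\\]", txt)) noteWarn(trimws(txt))
        invokeRestart("muffleMessage")
      })
    report$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  ## 1 - simulate -----------------------------------------------------------
  sim <- stage("simulate", {
    if (nzchar(config$stack_manifest)) {
      stack <- readStackManifest(config$stack_manifest)
      occPath <- config$occurrences
      smpPath <- config$samples
    } else {
      sc <- demoScene(seed, ncols = config$grid_ncols,
                      nrows = config$grid_nrows,
                      nOccurrences = config$n_occurrences,
                      nPresence = config$n_presence)
      stack <- sc$stack
      writeStackManifest(stack, file.path(out, "stack"))
      writeAsc(sc$suitability, file.path(out, "true_suitability.asc"))
      occPath <- file.path(out, "occurrences.csv")
      write.table(sc$occurrences, occPath, sep = ",", row.names = FALSE,
                  quote = FALSE)
      eqs <- builtinEquations()
      pts <- sampleOccurrences(sc$suitability, config$n_samples,
                               seed = splitSeed(seed, 3))
      noise <- calibrateNoiseSd(pts, stack, eqs,
                                targetR2 = config$target_r2)
      samples <- simulateCompoundContents(pts, stack, eqs, noise,
                                          seed = splitSeed(seed, 4))
      smpPath <- file.path(out, "samples.csv")
      write.table(samples, smpPath, sep = ",", row.names = FALSE,
                  quote = FALSE)
    }
    list(stack = stack, occPath = occPath, smpPath = smpPath)
  })
  stack <- sim$stack

  ## 2 - grid occurrences ---------------------------------------------------
  presence <- stage("grid", {
    occ <- read.table(sim$occPath, header = TRUE, sep = ",")
    trimPresence(gridOccurrences(occ, stack), config$n_presence)
  })
  report$nPresenceCells <- nPresence(presence)

  ## 3 - ensemble -----------------------------------------------------------
  rule <- screeningRule(config$precip_layer, config$elev_layer,
                        config$precip_low, config$precip_high,
                        config$elev_min)
  cfg <- fitConfig(treeComplexity = config$tree_complexity,
                   learningRate = config$learning_rate,
                   bagFraction = config$bag_fraction,
                   stepSize = config$step_size, nFolds = config$n_folds,
                   maxTrees = config$max_trees, minObs = config$min_obs,
                   patience = config$patience, seed = splitSeed(seed, 5))
  ens <- stage("ensemble", {
    runEnsemble(presence, stack, rule, cfg,
                nIterations = config$n_iterations,
                seed = splitSeed(seed, 6))
  })
  writeAsc(ens@meanSuitability, file.path(out, "suitability_mean.asc"))
  writeAsc(ens@sdSuitability, file.path(out, "suitability_sd.asc"))
  write.table(ens@rcTable, file.path(out, "rc_table.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  write.table(data.frame(iteration = seq_along(ens@aucPerIteration),
                         auc = ens@aucPerIteration,
                         n_trees = ens@nTreesPerIteration),
              file.path(out, "auc_per_iteration.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  report$nIterations <- ens@nIterations
  report$aucMean <- mean(ens@aucPerIteration)
  report$aucSd <- sd(ens@aucPerIteration)
  report$rcTable <- ens@rcTable

  ## 4 - quality regressions ------------------------------------------------
  qual <- stage("quality", {
    sel <- selectMainFactors(ens@rcTable, config$rc_threshold)
    kinds <- layerKinds(stack)
    candidates <- sel@selected$predictor[
      kinds[sel@selected$predictor] == "continuous"]
    samples <- read.table(sim$smpPath, header = TRUE, sep = ",")
    compounds <- setdiff(names(samples),
                         c("id", "lon", "lat", layerNames(stack)))
    eqs <- lapply(compounds, function(cmp)
      stepwiseRegression(samples[[cmp]],
                         samples[, candidates, drop = FALSE],
                         response = cmp))
    layers <- lapply(eqs, function(eq) applyEquation(eq, stack))
    # combined quality: mean of min-max normalized compound layers
    vm <- validMask(stack)
    normed <- lapply(layers, function(g) {
      v <- g@values; v[!vm] <- NA
      rng <- range(v, na.rm = TRUE)
      if (diff(rng) == 0) matrix(0.5, nrow(v), ncol(v))
      else (v - rng[1]) / diff(rng)
    })
    combined <- Reduce(`+`, normed) / length(normed)
    combined[!vm] <- NA
    for (i in seq_along(eqs))
      writeAsc(layers[[i]],
               file.path(out, paste0("content_", compounds[i], ".asc")))
    quality <- rasterGrid(gridHeader(stack), combined)
    writeAsc(quality, file.path(out, "quality_combined.asc"))
    list(selection = sel, equations = eqs, quality = quality)
  })
  report$mainFactors <- qual$selection@selected
  report$cumulativeRC <- qual$selection@cumulativeRC
  report$equations <- lapply(qual$equations, function(eq)
    list(response = eq@response, intercept = eq@intercept,
         coefficients = as.list(eq@coefficients), rSquared = eq@rSquared,
         n = eq@n))

  ## 5 - classify -----------------------------------------------------------
  cls <- stage("classify", {
    overlayQualitySuitability(ens@meanSuitability, qual$quality,
                              k = config$classes,
                              subsample = config$jenks_subsample,
                              combine = config$combine,
                              seed = splitSeed(seed, 8))
  })
  writeClassifiedMap(cls, file.path(out, "high_quality_classes"))
  report$breaks <- as.numeric(cls@breaks)
  report$classes <- cls@k

  jsonlite::write_json(report[setdiff(names(report), "stages")],
                       file.path(out, "report.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  class(report) <- "RunReport"
  logMsg("pipeline finished; outputs in ", out, file = logFile)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  output: %s\n", x$config$output_dir))
  cat(sprintf("  presence cells: %d; iterations: %d\n",
              x$nPresenceCells, x$nIterations))
  cat(sprintf("  held-out AUC: %.3f +/- %.3f\n", x$aucMean, x$aucSd))
  cat(sprintf("  main factors (%d, cumulative %.2f%%): %s\n",
              nrow(x$mainFactors), x$cumulativeRC,
              paste(x$mainFactors$predictor, collapse = ", ")))
  cat(sprintf("  class breaks: %s\n",
              paste(signif(x$breaks, 5), collapse = ", ")))
  if (length(x$warnings))
    cat(sprintf("  warnings: %d (see report.json)\n", length(x$warnings)))
  invisible(x)
}
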