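#' Header of an ESRI ASCII grid
#'
#' Georeferencing metadata shared by all raster layers in an analysis:
#' dimensions, lower-left corner, square cell size and the sentinel used for
#' missing cells. Follows the ESRI ASCII grid convention in which row 0 of the
#' value matrix is the northernmost row.
#'
#' @slot ncols number of columns (>= 1).
#' @slot nrows number of rows (>= 1).
#' @slot xllcorner x coordinate of the outer lower-left corner (map units).
#' @slot yllcorner y coordinate of the outer lower-left corner (map units).
#' @slot cellsize cell edge length (map units, > 0).
#' @slot nodata value marking missing cells (default -9999).
#' @export
setClass("GridHeader", representation(
  ncols = "integer", nrows = "integer",
  xllcorner = "numeric", yllcorner = "numeric",
  cellsize = "numeric", nodata = "numeric"
))

setValidity("GridHeader", function(object) {
  msg <- character()
  if (length(object@ncols) != 1 || is.na(object@ncols) || object@ncols < 1L)
    msg <- c(msg, "ncols must be a positive integer")
  if (length(object@nrows) != 1 || is.na(object@nrows) || object@nrows < 1L)
    msg <- c(msg, "nrows must be a positive integer")
  if (length(object@cellsize) != 1 || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GridHeader
#'
#' @param ncols,nrows grid dimensions.
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param cellsize cell edge length.
#' @param nodata nodata sentinel (default -9999, the ESRI default).
#' @return a [GridHeader-class] object.
#' @export
#' @examples
#' GridHeader(10, 10, 0, 0, 1)
GridHeader <- function(ncols, nrows, xllcorner = 0, yllcorner = 0,
                       cellsize = 1, nodata = -9999) {
  new("GridHeader", ncols = as.integer(ncols), nrows = as.integer(nrows),
      xllcorner = as.numeric(xllcorner), yllcorner = as.numeric(yllcorner),
      cellsize = as.numeric(cellsize), nodata = as.numeric(nodata))
}

#' Georeferenced single-layer raster
#'
#' A 2-D array of cell values plus its [GridHeader-class] and a logical mask
#' of missing cells. Row 1 of `values` is the northern edge. Masked cells
#' compare equal regardless of their stored value.
#'
#' @slot header a [GridHeader-class].
#' @slot values numeric matrix, `nrows x ncols`.
#' @slot mask logical matrix of the same shape; `TRUE` marks nodata.
#' @export
setClass("RasterGrid", representation(
  header = "GridHeader", values = "matrix", mask = "matrix"
))

setValidity("RasterGrid", function(object) {
  h <- object@header
  msg <- character()
  if (!identical(dim(object@values), c(h@nrows, h@ncols)))
    msg <- c(msg, sprintf("values must be %d x %d", h@nrows, h@ncols))
  if (!identical(dim(object@mask), dim(object@values)))
    msg <- c(msg, "mask must have the same shape as values")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param header a [GridHeader-class].
#' @param values numeric matrix (`nrows x ncols`, row 1 = north). `NA` entries
#'   are converted to masked cells.
#' @param mask optional logical matrix; defaults to `is.na(values)`.
#' @return a [RasterGrid-class].
#' @export
#' @examples
#' g <- rasterGrid(GridHeader(2, 2, 0, 0, 1), matrix(1:4, 2, 2))
rasterGrid <- function(header, values, mask = NULL) {
  values <- matrix(as.numeric(values), nrow = header@nrows,
                   ncol = header@ncols)
  if (is.null(mask)) mask <- is.na(values)
  values[mask] <- header@nodata
  new("RasterGrid", header = header, values = values, mask = mask)
}

#' Aligned multi-layer environment stack
#'
#' An ordered, named collection of [RasterGrid-class] layers sharing one
#' header, each flagged continuous or categorical. Categorical layers hold
#' integer codes on unmasked cells. The joint `validMask` marks cells that are
#' unmasked in every layer; all feature extraction uses it.
#'
#' @slot layers named list of [RasterGrid-class].
#' @slot kinds named character vector, one of `"continuous"`/`"categorical"`
#'   per layer.
#' @slot validMask logical matrix, `TRUE` where every layer has data.
#' @export
setClass("EnvStack", representation(
  layers = "list", kinds = "character", validMask = "matrix"
))

setValidity("EnvStack", function(object) {
  msg <- character()
  if (length(object@layers) < 1) msg <- c(msg, "stack needs >= 1 layer")
  if (is.null(names(object@layers)) || any(!nzchar(names(object@layers))))
    msg <- c(msg, "layers must be named")
  if (!identical(sort(names(object@layers)), sort(names(object@kinds))))
    msg <- c(msg, "kinds must name every layer")
  if (!all(object@kinds %in% c("continuous", "categorical")))
    msg <- c(msg, "kinds must be 'continuous' or 'categorical'")
  if (length(msg)) msg else TRUE
})

#' Unique presence cells derived from occurrence records
#'
#' Raw occurrence points snapped to grid cells, with within-cell duplicates
#' collapsed. `cells` holds (row, col) indices into the reference stack;
#' `counts` the number of raw records behind each cell.
#'
#' @slot cells integer matrix with columns `row`, `col`.
#' @slot counts integer vector, raw record count per cell.
#' @slot header the reference [GridHeader-class].
#' @export
setClass("PresenceGrid", representation(
  cells = "matrix", counts = "integer", header = "GridHeader"
))

setValidity("PresenceGrid", function(object) {
  msg <- character()
  if (ncol(object@cells) != 2) msg <- c(msg, "cells must have 2 columns")
  if (nrow(object@cells) != length(object@counts))
    msg <- c(msg, "one count per cell required")
  if (anyDuplicated(paste(object@cells[, 1], object@cells[, 2])))
    msg <- c(msg, "duplicate cells are not allowed")
  if (length(msg)) msg else TRUE
})

#' Background screening rule
#'
#' Cells are eligible as background (pseudo-absence) points when they violate
#' the suitable band: annual precipitation below `precipLow` or above
#' `precipHigh`, or elevation below `elevMin`. Defaults follow the published
#' agronomic rule for *Gentiana dahurica*: precipitation outside 250--400 mm
#' or elevation under 800 m marks a cell unsuitable. Boundary values are NOT
#' eligible (strict inequalities).
#'
#' @slot precipLayer,elevLayer layer names in the stack.
#' @slot precipLow,precipHigh precipitation band bounds (mm).
#' @slot elevMin minimum suitable elevation (m).
#' @export
setClass("ScreeningRule", representation(
  precipLayer = "character", precipLow = "numeric", precipHigh = "numeric",
  elevLayer = "character", elevMin = "numeric"
))

setValidity("ScreeningRule", function(object) {
  if (object@precipLow >= object@precipHigh)
    "precipLow must be < precipHigh" else TRUE
})

#' Construct a ScreeningRule
#' @param precipLayer,elevLayer names of the precipitation and elevation
#'   layers in the stack.
#' @param precipLow,precipHigh suitable precipitation band (mm); cells outside
#'   are background-eligible.
#' @param elevMin minimum suitable elevation (m); cells below are eligible.
#' @return a [ScreeningRule-class].
#' @export
#' @examples
#' screeningRule("bio4", "elev")
screeningRule <- function(precipLayer, elevLayer, precipLow = 250,
                          precipHigh = 400, elevMin = 800) {
  new("ScreeningRule", precipLayer = precipLayer, elevLayer = elevLayer,
      precipLow = as.numeric(precipLow), precipHigh = as.numeric(precipHigh),
      elevMin = as.numeric(elevMin))
}

#' Boosted regression tree fitting configuration
#'
#' Hyperparameters of the Bernoulli-deviance gradient-boosting fit. The
#' defaults are the published settings for the *G. dahurica* ensemble:
#' `treeComplexity = 4` splits per tree, `learningRate = 0.005`,
#' `bagFraction = 0.75`, `stepSize = 10` trees per growth step, 10-fold
#' cross-validation. `patience` is the number of consecutive non-improving
#' steps tolerated before tree growth stops.
#'
#' @slot treeComplexity splits per tree.
#' @slot learningRate shrinkage applied to each tree's contribution.
#' @slot bagFraction fraction of rows subsampled (without replacement) per
#'   boosting iteration.
#' @slot stepSize trees added per cross-validation growth step.
#' @slot nFolds number of CV folds.
#' @slot maxTrees hard cap on the number of trees grown.
#' @slot minObs minimum observations in a child node.
#' @slot patience non-improving CV steps before stopping.
#' @slot seed RNG seed for folds and bagging.
#' @export
setClass("FitConfig", representation(
  treeComplexity = "integer", learningRate = "numeric",
  bagFraction = "numeric", stepSize = "integer", nFolds = "integer",
  maxTrees = "integer", minObs = "integer", patience = "integer",
  seed = "numeric"
))

setValidity("FitConfig", function(object) {
  msg <- character()
  if (object@stepSize < 1L) msg <- c(msg, "stepSize must be >= 1")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@bagFraction <= 0 || object@bagFraction > 1)
    msg <- c(msg, "bagFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a FitConfig
#' @param treeComplexity,learningRate,bagFraction,stepSize,nFolds,maxTrees,minObs,patience,seed
#'   see [FitConfig-class].
#' @return a [FitConfig-class].
#' @export
#' @examples
#' fitConfig(maxTrees = 500, seed = 7)
fitConfig <- function(treeComplexity = 4, learningRate = 0.005,
                      bagFraction = 0.75, stepSize = 10, nFolds = 10,
                      maxTrees = 10000, minObs = 10, patience = 5, seed = 1) {
  new("FitConfig", treeComplexity = as.integer(treeComplexity),
      learningRate = as.numeric(learningRate),
      bagFraction = as.numeric(bagFraction), stepSize = as.integer(stepSize),
      nFolds = as.integer(nFolds), maxTrees = as.integer(maxTrees),
      minObs = as.integer(minObs), patience = as.integer(patience),
      seed = as.numeric(seed))
}

#' Boosted regression trees model
#'
#' An additive sequence of depth-limited regression trees fitted to the
#' Bernoulli-deviance gradient. The score of a row is
#' `initialScore + learningRate * sum(tree outputs)` over the first
#' `nTreesUsed` trees; the predicted presence probability is its logistic.
#' Each split node records its squared-error improvement, from which relative
#' influence is computed.
#'
#' @slot initialScore intercept on the log-odds scale (`log(p/(1-p))` of the
#'   training prevalence).
#' @slot trees list of fitted trees (flat node arrays; see [fitBRT]).
#' @slot learningRate,treeComplexity,bagFraction as fitted.
#' @slot nTreesUsed number of leading trees used for prediction.
#' @slot predictors training predictor names, in column order.
#' @slot kinds named kind per predictor (`"continuous"`/`"categorical"`).
#' @slot nTrain number of training rows.
#' @export
setClass("BoostedTreesModel", representation(
  initialScore = "numeric", trees = "list", learningRate = "numeric",
  treeComplexity = "integer", bagFraction = "numeric",
  nTreesUsed = "integer", predictors = "character", kinds = "character",
  nTrain = "integer"
))

setValidity("BoostedTreesModel", function(object) {
  msg <- character()
  if (object@nTreesUsed > length(object@trees))
    msg <- c(msg, "nTreesUsed exceeds the number of fitted trees")
  if (!all(object@kinds %in% c("continuous", "categorical")))
    msg <- c(msg, "kinds must be 'continuous' or 'categorical'")
  if (length(msg)) msg else TRUE
})

#' Aggregated results of a background-resampled BRT ensemble
#'
#' @slot meanSuitability cell-wise mean predicted suitability in `[0, 1]`.
#' @slot sdSuitability cell-wise population standard deviation across
#'   iterations (the prediction-uncertainty surface).
#' @slot rcTable data.frame `predictor`, `mean`, `sd`: relative contribution
#'   (%) averaged over iterations; means sum to 100.
#' @slot aucPerIteration mean held-out cross-validated AUC per iteration.
#' @slot nTreesPerIteration selected tree count per iteration.
#' @slot nIterations number of successful iterations.
#' @slot nFailed number of skipped (failed) iterations.
#' @export
setClass("EnsembleSummary", representation(
  meanSuitability = "RasterGrid", sdSuitability = "RasterGrid",
  rcTable = "data.frame", aucPerIteration = "numeric",
  nTreesPerIteration = "integer", nIterations = "integer",
  nFailed = "integer"
))

#' A fitted or published compound-content regression equation
#'
#' Linear model `content = intercept + sum(coefficients * predictors)`.
#' Externally supplied (published) equations may carry an `rSquared` recorded
#' from their source and empty `pValues`.
#'
#' @slot response compound name.
#' @slot intercept intercept.
#' @slot coefficients named coefficient vector (may be empty for an
#'   intercept-only model).
#' @slot rSquared coefficient of determination (`NA` if unknown).
#' @slot n number of fitting observations (`NA` if external).
#' @slot pValues named per-term p-values (empty if external).
#' @export
setClass("RegressionEquation", representation(
  response = "character", intercept = "numeric", coefficients = "numeric",
  rSquared = "numeric", n = "integer", pValues = "numeric"
))

setValidity("RegressionEquation", function(object) {
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    "rSquared must lie in [0, 1]" else TRUE
})

#' Construct a RegressionEquation
#' @param response compound name.
#' @param intercept model intercept.
#' @param coefficients named numeric vector of slopes (possibly empty).
#' @param rSquared R-squared (`NA` if unknown).
#' @param n fitting sample size (`NA` if external).
#' @param pValues named per-term p-values.
#' @return a [RegressionEquation-class].
#' @export
#' @examples
#' regressionEquation("sweroside", -0.05, c(bio4 = 0.000352))
regressionEquation <- function(response, intercept, coefficients = numeric(),
                               rSquared = NA_real_, n = NA_integer_,
                               pValues = numeric()) {
  new("RegressionEquation", response = response,
      intercept = as.numeric(intercept),
      coefficients = vapply(coefficients, as.numeric, 0),
      rSquared = as.numeric(rSquared), n = as.integer(n),
      pValues = vapply(pValues, as.numeric, 0))
}

#' Natural-breaks classified raster
#'
#' Integer class raster (1 = least suitable, `k` = most) with the Jenks break
#' values (class maxima of the first `k - 1` classes) and any normalization
#' constants used to build the classified quantity.
#'
#' @slot classes [RasterGrid-class] of integer codes `1..k`.
#' @slot breaks ascending numeric vector, length `k - 1`.
#' @slot k number of classes.
#' @slot info list of provenance details (normalization ranges, combine rule,
#'   subsampling).
#' @export
setClass("ClassifiedMap", representation(
  classes = "RasterGrid", breaks = "numeric", k = "integer", info = "list"
))

setValidity("ClassifiedMap", function(object) {
  msg <- character()
  if (length(object@breaks) != object@k - 1L)
    msg <- c(msg, "breaks must have length k - 1")
  if (is.unsorted(object@breaks, strictly = TRUE))
    msg <- c(msg, "breaks must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic true-suitability surface
#'
#' The generator's ground truth mirrors the qualitative ecology reported for
#' *G. dahurica*: suitability rises with elevation (crossing its midpoint at
#' `elevationThreshold`, default 1500 m), plateaus inside the annual
#' precipitation band (default 250--400 mm) and decays outside it, and shifts
#' by a per-code offset on one categorical (soil/vegetation) layer.
#' Suitability is
#' `plogis(logisticScale * (elevAmplitude * s_elev + precipAmplitude * s_precip + catEffect))`
#' where `s_elev = plogis((elev - elevationThreshold)/elevWidth) - 1/2` and
#' `s_precip = exp(-d^2/(2 precipWidth^2)) - 1/2` with `d` the distance to the
#' band (0 inside). Setting both amplitudes and all categorical effects to 0
#' gives a uniform 0.5 surface.
#'
#' @slot elevLayer,precipLayer,catLayer layer names.
#' @slot elevationThreshold elevation (m) at which the elevation effect
#'   crosses its midpoint.
#' @slot precipBand suitable precipitation band `(low, high)` in mm.
#' @slot logisticScale overall signal strength (> 0).
#' @slot elevWidth,precipWidth smoothness scales (m, mm).
#' @slot elevAmplitude,precipAmplitude effect amplitudes (default 1).
#' @slot categoricalEffects named (by code) additive offsets for `catLayer`;
#'   codes not listed get 0.
#' @slot seed master seed used by scene helpers.
#' @export
setClass("TruthParams", representation(
  elevLayer = "character", precipLayer = "character", catLayer = "character",
  elevationThreshold = "numeric", precipBand = "numeric",
  logisticScale = "numeric", elevWidth = "numeric", precipWidth = "numeric",
  elevAmplitude = "numeric", precipAmplitude = "numeric",
  categoricalEffects = "numeric", seed = "numeric"
))

setValidity("TruthParams", function(object) {
  msg <- character()
  if (length(object@precipBand) != 2 ||
      object@precipBand[1] >= object@precipBand[2])
    msg <- c(msg, "precipBand must be (low, high) with low < high")
  if (object@logisticScale <= 0) msg <- c(msg, "logisticScale must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct TruthParams
#' @param elevLayer,precipLayer,catLayer layer names in the stack.
#' @param elevationThreshold,precipBand,logisticScale,elevWidth,precipWidth,elevAmplitude,precipAmplitude,categoricalEffects,seed
#'   see [TruthParams-class].
#' @return a [TruthParams-class].
#' @export
#' @examples
#' truthParams("elev", "bio4", "soil")
truthParams <- function(elevLayer, precipLayer, catLayer,
                        elevationThreshold = 1500, precipBand = c(250, 400),
                        logisticScale = 6, elevWidth = 200, precipWidth = 75,
                        elevAmplitude = 1, precipAmplitude = 1,
                        categoricalEffects = numeric(), seed = 1) {
  new("TruthParams", elevLayer = elevLayer, precipLayer = precipLayer,
      catLayer = catLayer,
      elevationThreshold = as.numeric(elevationThreshold),
      precipBand = as.numeric(precipBand),
      logisticScale = as.numeric(logisticScale),
      elevWidth = as.numeric(elevWidth), precipWidth = as.numeric(precipWidth),
      elevAmplitude = as.numeric(elevAmplitude),
      precipAmplitude = as.numeric(precipAmplitude),
      categoricalEffects = categoricalEffects, seed = as.numeric(seed))
}
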