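#' @name accessors
#' @title Accessors for spatial containers
#' @description Slot access for [RasterGrid-class], [EnvStack-class] and
#'   friends goes through these generics; downstream code never touches slots
#'   directly.
#' @param x object.
#' @param name layer name.
#' @return `gridValues`/`gridMask` return matrices, `gridHeader` a
#'   [GridHeader-class], `layerNames`/`layerKinds` character vectors,
#'   `getLayer` a [RasterGrid-class], `validMask` a logical matrix,
#'   `nLayers`/`nPresence` integers, `presenceCells` an integer matrix.
NULL

#' @rdname accessors
#' @export
setGeneric("gridHeader", function(x) standardGeneric("gridHeader"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("gridMask", function(x) standardGeneric("gridMask"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setGeneric("layerKinds", function(x) standardGeneric("layerKinds"))
#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setGeneric("presenceCells", function(x) standardGeneric("presenceCells"))
#' @rdname accessors
#' @export
setGeneric("nPresence", function(x) standardGeneric("nPresence"))

#' @rdname accessors
#' @export
setMethod("gridHeader", "RasterGrid", function(x) x@header)
#' @rdname accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) {
  v <- x@values
  v[x@mask] <- NA_real_
  v
})
#' @rdname accessors
#' @export
setMethod("gridMask", "RasterGrid", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("gridHeader", "EnvStack", function(x) x@layers[[1]]@header)
#' @rdname accessors
#' @export
setMethod("layerNames", "EnvStack", function(x) names(x@layers))
#' @rdname accessors
#' @export
setMethod("layerKinds", "EnvStack", function(x) x@kinds[names(x@layers)])
#' @rdname accessors
#' @export
setMethod("getLayer", "EnvStack", function(x, name) {
  if (!name %in% names(x@layers))
    stop("layer '", name, "' not in stack (has: ",
         paste(names(x@layers), collapse = ", "), ")")
  x@layers[[name]]
})
#' @rdname accessors
#' @export
setMethod("validMask", "EnvStack", function(x) x@validMask)
#' @rdname accessors
#' @export
setMethod("nLayers", "EnvStack", function(x) length(x@layers))
#' @rdname accessors
#' @export
setMethod("presenceCells", "PresenceGrid", function(x) x@cells)
#' @rdname accessors
#' @export
setMethod("nPresence", "PresenceGrid", function(x) nrow(x@cells))

setMethod("show", "GridHeader", function(object) {
  cat(sprintf("GridHeader: %d cols x %d rows, cellsize %g, ll (%g, %g), nodata %g\n",
              object@ncols, object@nrows, object@cellsize,
              object@xllcorner, object@yllcorner, object@nodata))
})

setMethod("show", "RasterGrid", function(object) {
  h <- object@header
  v <- object@values[!object@mask]
  cat(sprintf("RasterGrid %d x %d (cellsize %g), %d/%d valid cells\n",
              h@nrows, h@ncols, h@cellsize, length(v), h@nrows * h@ncols))
  if (length(v))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g\n",
                min(v), mean(v), max(v)))
})

setMethod("show", "EnvStack", function(object) {
  h <- gridHeader(object)
  cat(sprintf("EnvStack of %d layers, %d x %d, %d jointly valid cells\n",
              length(object@layers), h@nrows, h@ncols, sum(object@validMask)))
  for (nm in names(object@layers))
    cat(sprintf("  %-12s %s\n", nm, object@kinds[[nm]]))
})

setMethod("show", "PresenceGrid", function(object) {
  cat(sprintf("PresenceGrid: %d unique cells from %d records\n",
              nrow(object@cells), sum(object@counts)))
})

setMethod("show", "BoostedTreesModel", function(object) {
  cat(sprintf(paste0("BoostedTreesModel: %d trees (%d used), lr %g, ",
                     "complexity %d, bag %g\n"),
              length(object@trees), object@nTreesUsed, object@learningRate,
              object@treeComplexity, object@bagFraction))
  cat(sprintf("  predictors: %s\n", paste(object@predictors, collapse = ", ")))
})

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary over %d iterations (%d failed)\n",
              object@nIterations, object@nFailed))
  cat(sprintf("  held-out AUC: %.3f +/- %.3f\n",
              mean(object@aucPerIteration), sd(object@aucPerIteration)))
  rc <- object@rcTable[order(-object@rcTable$mean), ]
  cat("  top contributions:\n")
  for (i in seq_len(min(5, nrow(rc))))
    cat(sprintf("    %-12s %6.2f%%\n", rc$predictor[i], rc$mean[i]))
})

setMethod("show", "RegressionEquation", function(object) {
  terms <- if (length(object@coefficients))
    paste(sprintf("%+g*%s", object@coefficients,
                  names(object@coefficients)), collapse = " ")
  else "(intercept only)"
  cat(sprintf("%s = %g %s", object@response, object@intercept, terms))
  if (!is.na(object@rSquared)) cat(sprintf("  (R2 = %.3f)", object@rSquared))
  cat("\n")
})

setMethod("show", "ClassifiedMap", function(object) {
  cat(sprintf("ClassifiedMap with %d classes; breaks: %s\n", object@k,
              paste(signif(object@breaks, 6), collapse = ", ")))
})

setMethod("show", "ScreeningRule", function(object) {
  cat(sprintf(
    "ScreeningRule: background iff %s < %g or > %g, or %s < %g\n",
    object@precipLayer, object@precipLow, object@precipHigh,
    object@elevLayer, object@elevMin))
})
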