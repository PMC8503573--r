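#' Jenks natural breaks
#'
#' Exact Fisher-Jenks dynamic programme: partitions the sorted values into
#' `k` contiguous classes minimizing the total within-class sum of squared
#' deviations from the class means ("minimize the differences within groups,
#' maximize the differences between groups"). Breaks are the maximum value
#' of each of the first `k - 1` classes.
#'
#' @param values numeric vector.
#' @param k number of classes (>= 2, <= number of distinct values).
#' @return ascending numeric vector of `k - 1` breaks, with the achieved
#'   within-class SSD as attribute `"ssd"`.
#' @export
#' @examples
#' jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)  # break at 3
jenksBreaks <- function(values, k) {
  values <- values[is.finite(values)]
  if (k < 2) stop("k must be >= 2")
  if (length(unique(values)) < k)
    stop("need at least k distinct values (have ",
         length(unique(values)), ", k = ", k, ")")
  res <- cpp_jenks(sort(values), as.integer(k))
  breaks <- res$breaks
  attr(breaks, "ssd") <- res$ssd
  breaks
}

#' Classify a raster by break values
#'
#' Class of a cell is `1 + number of breaks strictly below its value`,
#' capped at `k = length(breaks) + 1`; a value exactly equal to a break gets
#' the lower class (breaks are class maxima). Nodata propagates.
#'
#' @param grid a [RasterGrid-class].
#' @param breaks ascending numeric vector.
#' @return a [ClassifiedMap-class].
#' @export
classifyRaster <- function(grid, breaks) {
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly ascending")
  v <- grid@values
  cls <- matrix(1, nrow(v), ncol(v))
  for (b in breaks) cls <- cls + (v > b)
  cls[grid@mask] <- NA
  new("ClassifiedMap",
      classes = rasterGrid(grid@header, cls),
      breaks = as.numeric(breaks), k = length(breaks) + 1L,
      info = list())
}

#' Overlay quality on suitability and classify
#'
#' Both layers are min-max normalized to `[0, 1]` over jointly unmasked
#' cells, combined cell-wise (product by default: a high-quality growing
#' area must score high on both; `"min"` is the conservative alternative),
#' and the combined score is cut into `k` classes by exact Jenks breaks.
#' When the raster holds more than `subsample` valid cells the breaks are
#' computed on a seeded random subsample of that size (the DP is quadratic);
#' at or below the threshold the exact full-data partition is used.
#'
#' @param suitability,quality [RasterGrid-class] layers with identical
#'   headers.
#' @param k number of classes (default 4).
#' @param subsample maximum number of cells used for break computation.
#' @param combine `"product"` or `"min"`.
#' @param seed RNG seed for the subsample.
#' @return a [ClassifiedMap-class]; `info` records the normalization ranges,
#'   combine rule, and whether subsampling occurred.
#' @export
overlayQualitySuitability <- function(suitability, quality, k = 4,
                                      subsample = 10000,
                                      combine = c("product", "min"),
                                      seed = 1) {
  combine <- match.arg(combine)
  d <- headersEqual(suitability@header, quality@header)
  if (length(d))
    stop("layers are not aligned: differing header field(s) ",
         paste(d, collapse = ", "))
  mask <- suitability@mask | quality@mask
  norm <- function(g, label) {
    v <- g@values
    v[mask] <- NA
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0)
      stop("cannot normalize constant layer '", label, "' (zero range)")
    list(v = (v - rng[1]) / diff(rng), rng = rng)
  }
  ns <- norm(suitability, "suitability")
  nq <- norm(quality, "quality")
  comb <- if (combine == "product") ns$v * nq$v else pmin(ns$v, nq$v)
  vals <- comb[!mask]
  sub <- length(vals) > subsample
  if (sub)
    vals <- withSeed(splitSeed(seed, 31), sample(vals, subsample))
  breaks <- jenksBreaks(vals, k)
  out <- classifyRaster(rasterGrid(suitability@header, comb), breaks)
  out@info <- list(combine = combine,
                   suitabilityRange = ns$rng, qualityRange = nq$rng,
                   subsampled = sub,
                   nCellsUsed = length(vals), breaks = as.numeric(breaks))
  out
}

#' Write a classified map with its JSON sidecar
#'
#' The class raster goes to `<path>.asc`; breaks, class count and the
#' overlay provenance (`info`) go to `<path>.json`.
#'
#' @param map a [ClassifiedMap-class].
#' @param path output path stem (no extension).
#' @return the raster path, invisibly.
#' @export
writeClassifiedMap <- function(map, path) {
  writeAsc(map@classes, paste0(path, ".asc"))
  jsonlite::write_json(
    c(list(k = map@k, breaks = as.numeric(map@breaks)), map@info),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(paste0(path, ".asc"))
}
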