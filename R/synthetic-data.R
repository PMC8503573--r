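#' Generate a synthetic environment stack
#'
#' Builds named raster layers with the statistical structure the analysis
#' assumes of real climate/soil data. Continuous layers are a linear spatial
#' gradient plus a Gaussian random field smoothed by a moving-average box
#' filter (which induces spatial autocorrelation) and rescaled to the stated
#' noise SD. Categorical layers are nearest-seed-point (Voronoi) integer
#' patches with codes `1..k`. Layer RNG streams are derived from the master
#' seed via [splitSeed], so the result is fully deterministic.
#'
#' @param header a [GridHeader-class] for all layers.
#' @param layerSpec list of per-layer specs. Continuous:
#'   `list(name=, kind="continuous", mean=, sd=, gradientAmplitude=,
#'   gradientAngle=, smoothWidth=)` (angle in degrees: 0 = increasing
#'   west-to-east, 90 = south-to-north; the gradient spans
#'   `[-amplitude/2, +amplitude/2]` across the grid; smoothWidth defaults to
#'   3 cells). Categorical: `list(name=, kind="categorical", k=)`.
#' @param seed master seed.
#' @return an [EnvStack-class].
#' @export
#' @examples
#' st <- generateEnvStack(GridHeader(16, 16, cellsize = 1000),
#'                        demoLayerSpec(), seed = 1)
generateEnvStack <- function(header, layerSpec, seed) {
  if (length(layerSpec) == 0) stop("layerSpec must name at least one layer")
  nr <- header@nrows; nc <- header@ncols
  # normalized coordinates of cell centers: u west->east, v south->north
  u <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  v <- matrix(rep((nr - seq_len(nr) + 0.5) / nr, times = nc), nr, nc)
  grids <- list(); kinds <- character()
  for (i in seq_along(layerSpec)) {
    sp <- layerSpec[[i]]
    if (is.null(sp$name) || is.null(sp$kind))
      stop("each layer spec needs 'name' and 'kind'")
    subseed <- splitSeed(seed, i)
    if (sp$kind == "continuous") {
      amp <- if (is.null(sp$gradientAmplitude)) 0 else sp$gradientAmplitude
      ang <- if (is.null(sp$gradientAngle)) 0 else sp$gradientAngle * pi / 180
      w <- if (is.null(sp$smoothWidth)) 3L else as.integer(sp$smoothWidth)
      grad <- amp * ((cos(ang) * u + sin(ang) * v -
                        0.5 * (cos(ang) + sin(ang))))
      noise <- withSeed(subseed, matrix(rnorm(nr * nc), nr, nc))
      noise <- boxSmooth(noise, w)
      s <- stats::sd(noise)
      if (sp$sd > 0 && s > 0) noise <- noise * (sp$sd / s) else noise[] <- 0
      vals <- sp$mean + grad + noise
    } else if (sp$kind == "categorical") {
      k <- sp$k
      if (is.null(k) || k < 1) stop("categorical layer needs k >= 1")
      pts <- withSeed(subseed, cbind(runif(k), runif(k)))
      d2 <- array(0, dim = c(nr, nc, k))
      for (j in seq_len(k))
        d2[, , j] <- (u - pts[j, 1])^2 + (v - pts[j, 2])^2
      vals <- apply(d2, c(1, 2), which.min)
    } else stop("unknown layer kind '", sp$kind, "'")
    grids[[sp$name]] <- rasterGrid(header, vals)
    kinds[[sp$name]] <- sp$kind
  }
  buildStack(grids, kinds)
}

# Moving-average box filter of odd width, separable, with edge windows
# truncated and renormalized.
boxSmooth <- function(m, width) {
  if (width <= 1) return(m)
  half <- (width - 1) %/% 2
  smooth1 <- function(x) {
    n <- length(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  m <- apply(m, 2, smooth1)
  t(apply(m, 1, smooth1))
}

#' Default layer specification for the demonstration scene
#'
#' Six layers echoing the structure of the real predictor set: annual mean
#' temperature (`bio1`, deg C), temperature seasonality (`bio3`, SD x 100),
#' annual precipitation (`bio4`, mm), elevation (`elev`, m), a categorical
#' soil-type layer (`soil`, 5 Voronoi patches) and an inert solar-radiation
#' layer (`srad`). Gradients and noise levels are chosen so that the
#' background-screening band (precipitation outside 250--400 mm or elevation
#' under 800 m) covers a substantial fraction of the scene, and so that the
#' published content-regression slopes yield realistic percent-dry-mass
#' contents.
#'
#' @return a list of layer specs for [generateEnvStack].
#' @export
demoLayerSpec <- function() {
  list(
    list(name = "bio1", kind = "continuous", mean = 5, sd = 1.2,
         gradientAmplitude = 4, gradientAngle = 45),
    list(name = "bio3", kind = "continuous", mean = 1250, sd = 130,
         gradientAmplitude = 400, gradientAngle = 90),
    list(name = "bio4", kind = "continuous", mean = 325, sd = 45,
         gradientAmplitude = 260, gradientAngle = 0),
    list(name = "elev", kind = "continuous", mean = 1300, sd = 130,
         gradientAmplitude = 1100, gradientAngle = 90),
    list(name = "soil", kind = "categorical", k = 5),
    list(name = "srad", kind = "continuous", mean = 5500, sd = 300,
         gradientAmplitude = 0)
  )
}

#' Compute the known true-suitability surface
#'
#' Evaluates the generator's ground-truth habitat model (see
#' [TruthParams-class]) on every jointly valid cell of the stack:
#' a logistic of the sum of a smooth elevation effect (crossing its midpoint
#' at the elevation threshold), a precipitation plateau (maximal inside the
#' band, decaying outside) and a per-code categorical offset. Values lie in
#' `[0, 1]`; nodata propagates.
#'
#' @param stack an [EnvStack-class].
#' @param params a [TruthParams-class].
#' @return a [RasterGrid-class] of suitabilities.
#' @export
computeTrueSuitability <- function(stack, params) {
  for (nm in c(params@elevLayer, params@precipLayer, params@catLayer))
    if (!nm %in% layerNames(stack))
      stop("truth layer '", nm, "' missing from stack")
  elev <- getLayer(stack, params@elevLayer)@values
  prec <- getLayer(stack, params@precipLayer)@values
  cat_ <- getLayer(stack, params@catLayer)@values
  sElev <- plogis((elev - params@elevationThreshold) / params@elevWidth) - 0.5
  lo <- params@precipBand[1]; hi <- params@precipBand[2]
  d <- pmax(lo - prec, prec - hi, 0)
  sPrec <- exp(-d^2 / (2 * params@precipWidth^2)) - 0.5
  eff <- rep(0, length(cat_))
  if (length(params@categoricalEffects)) {
    idx <- match(as.character(cat_), names(params@categoricalEffects))
    eff <- ifelse(is.na(idx), 0, params@categoricalEffects[idx])
  }
  s <- plogis(params@logisticScale *
                (params@elevAmplitude * sElev +
                 params@precipAmplitude * sPrec + eff))
  vals <- matrix(s, nrow(elev), ncol(elev))
  vals[!validMask(stack)] <- NA
  rasterGrid(gridHeader(stack), vals)
}

#' Sample occurrence points from a suitability surface
#'
#' Draws `n` points from unmasked cells with probability proportional to
#' suitability (with replacement, so duplicate cells occur and exercise
#' deduplication downstream), then jitters each point uniformly inside its
#' cell.
#'
#' @param suitability a [RasterGrid-class] with non-negative values.
#' @param n number of points.
#' @param seed RNG seed.
#' @return data.frame `id`, `lon`, `lat`.
#' @export
sampleOccurrences <- function(suitability, n, seed) {
  h <- suitability@header
  ok <- which(!suitability@mask)
  w <- suitability@values[ok]
  if (all(w <= 0)) stop("cannot sample: suitability is zero everywhere")
  withSeed(splitSeed(seed, 7), {
    pick <- sample(ok, n, replace = TRUE, prob = w)
    rc <- arrayInd(pick, dim(suitability@values))
    ctr <- pointFromCell(h, rc[, 1], rc[, 2])
    jx <- runif(n, -0.5, 0.5) * h@cellsize
    jy <- runif(n, -0.5, 0.5) * h@cellsize
    data.frame(id = seq_len(n), lon = ctr[, "x"] + jx, lat = ctr[, "y"] + jy)
  })
}

#' Calibrate compound noise SDs to a target R-squared
#'
#' Sets each compound's Gaussian noise SD so that regressing the simulated
#' content on its true predictors recovers approximately `targetR2`:
#' `sd_noise = sd_signal * sqrt((1 - R2)/R2)`, where `sd_signal` is the SD of
#' the noiseless equation output over the given sample points. The default
#' target (0.35) sits mid-range of the published content-regression fits
#' (R-squared 0.304--0.365).
#'
#' @param points data.frame with `lon`, `lat`.
#' @param stack an [EnvStack-class].
#' @param equations list of [RegressionEquation-class] used as truth.
#' @param targetR2 target coefficient of determination.
#' @return named numeric vector of noise SDs.
#' @export
calibrateNoiseSd <- function(points, stack, equations, targetR2 = 0.35) {
  cells <- cellFromPoint(gridHeader(stack), points$lon, points$lat)
  keep <- !is.na(cells[, 1])
  keep[keep] <- validMask(stack)[cells[keep, , drop = FALSE]]
  cells <- cells[keep, , drop = FALSE]
  sds <- vapply(equations, function(eq) {
    sig <- rep(eq@intercept, nrow(cells))
    for (nm in names(eq@coefficients))
      sig <- sig + eq@coefficients[[nm]] * getLayer(stack, nm)@values[cells]
    s <- stats::sd(sig)
    if (!is.finite(s) || s == 0) s <- 1e-6
    s * sqrt((1 - targetR2) / targetR2)
  }, 0, USE.NAMES = FALSE)
  stats::setNames(sds, vapply(equations, function(e) e@response, ""))
}

#' Simulate compound-content sample tables
#'
#' Evaluates each truth equation at every point's cell predictor values and
#' adds Gaussian noise. Points falling off-grid or on nodata cells are
#' skipped with a logged count; contents are clipped at 0 from below with a
#' logged count (contents are percentages of dry mass and cannot be
#' negative). Deterministic given the seed.
#'
#' @param points data.frame with `lon`, `lat` (optional `id`).
#' @param stack an [EnvStack-class].
#' @param equations list of [RegressionEquation-class] used as truth.
#' @param noiseSd named numeric vector of per-compound noise SDs (names =
#'   equation responses); see [calibrateNoiseSd].
#' @param seed RNG seed.
#' @return data.frame `id`, `lon`, `lat`, one column per compound, one per
#'   predictor layer, with attributes `nSkipped` and `nClipped`.
#' @export
simulateCompoundContents <- function(points, stack, equations, noiseSd,
                                     seed) {
  for (eq in equations)
    for (nm in names(eq@coefficients))
      if (!nm %in% layerNames(stack))
        stop("equation predictor '", nm, "' missing from stack")
  h <- gridHeader(stack)
  cells <- cellFromPoint(h, points$lon, points$lat)
  vm <- validMask(stack)
  onGrid <- !is.na(cells[, 1])
  valid <- onGrid
  valid[onGrid] <- vm[cells[onGrid, , drop = FALSE]]
  nSkipped <- sum(!valid)
  if (nSkipped > 0)
    logMsg(nSkipped, " sample point(s) off-grid or on nodata; skipped",
           level = "WARN")
  cells <- cells[valid, , drop = FALSE]
  pts <- points[valid, , drop = FALSE]
  n <- nrow(pts)
  pred <- vapply(layerNames(stack), function(nm)
    getLayer(stack, nm)@values[cells], numeric(n))
  pred <- matrix(pred, nrow = n,
                 dimnames = list(NULL, layerNames(stack)))
  out <- data.frame(id = if ("id" %in% names(pts)) pts$id else seq_len(n),
                    lon = pts$lon, lat = pts$lat)
  nClipped <- 0L
  withSeed(splitSeed(seed, 11), {
    for (eq in equations) {
      mu <- eq@intercept
      for (nm in names(eq@coefficients))
        mu <- mu + eq@coefficients[[nm]] * pred[, nm]
      sdv <- noiseSd[[eq@response]]
      if (is.null(sdv)) stop("no noiseSd for compound '", eq@response, "'")
      y <- mu + rnorm(n, 0, sdv)
      nClipped <- nClipped + sum(y < 0)
      out[[eq@response]] <- pmax(y, 0)
    }
  })
  if (nClipped > 0)
    logMsg(nClipped, " simulated content value(s) clipped at 0",
           level = "WARN")
  out <- cbind(out, as.data.frame(pred))
  attr(out, "nSkipped") <- nSkipped
  attr(out, "nClipped") <- nClipped
  out
}

#' Build the demonstration scene
#'
#' One call that assembles the study conditions used throughout the package's
#' examples and checks: a 32 x 32 km synthetic stack ([demoLayerSpec]), the
#' ground-truth suitability surface (elevation threshold 1500 m,
#' precipitation band 250--400 mm, logistic scale 6, small soil-code
#' offsets), occurrence records sampled from the truth, a presence grid
#' trimmed to `nPresence` distinct cells (in sampling order), and the default
#' background screening rule.
#'
#' @param seed master seed.
#' @param ncols,nrows grid size (cells of 1000 m).
#' @param nOccurrences raw occurrence points drawn.
#' @param nPresence distinct presence cells kept.
#' @return list with `stack`, `truth`, `suitability`, `occurrences`,
#'   `presence`, `rule`.
#' @export
#' @examples
#' sc <- demoScene(seed = 1, ncols = 16, nrows = 16, nOccurrences = 60,
#'                 nPresence = 25)
demoScene <- function(seed, ncols = 32, nrows = 32, nOccurrences = 200,
                      nPresence = 60) {
  header <- GridHeader(ncols, nrows, 0, 0, 1000)
  stack <- generateEnvStack(header, demoLayerSpec(), seed = splitSeed(seed, 1))
  truth <- truthParams(
    elevLayer = "elev", precipLayer = "bio4", catLayer = "soil",
    categoricalEffects = c("1" = 0.25, "2" = 0, "3" = -0.25,
                           "4" = 0.1, "5" = -0.1),
    seed = seed)
  suit <- computeTrueSuitability(stack, truth)
  occ <- sampleOccurrences(suit, nOccurrences, seed = splitSeed(seed, 2))
  presence <- trimPresence(gridOccurrences(occ, stack), nPresence)
  list(stack = stack, truth = truth, suitability = suit, occurrences = occ,
       presence = presence, rule = screeningRule("bio4", "elev"))
}
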