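#' Partial F test for nested linear models
#'
#' The entry/removal criterion behind stepwise selection:
#' `F = ((rssReduced - rssFull)/dfAdded) / (rssFull/(n - pFull - 1))` with the
#' p-value from the upper tail of the F distribution on
#' `(dfAdded, n - pFull - 1)` degrees of freedom.
#'
#' @param rssReduced residual sum of squares of the smaller model.
#' @param rssFull residual sum of squares of the larger model.
#' @param dfAdded number of added terms.
#' @param n sample size.
#' @param pFull number of slope terms in the larger model.
#' @return list with `F` and `p`.
#' @export
#' @examples
#' partialFTest(10, 5, 1, 13, 2)  # F = 10
partialFTest <- function(rssReduced, rssFull, dfAdded, n, pFull) {
  if (rssFull <= 0 || rssReduced < rssFull)
    stop("need rssReduced >= rssFull > 0")
  df2 <- n - pFull - 1
  if (dfAdded < 1 || df2 < 1) stop("non-positive degrees of freedom")
  F <- ((rssReduced - rssFull) / dfAdded) / (rssFull / df2)
  list(F = F, p = pf(F, dfAdded, df2, lower.tail = FALSE))
}

rssOf <- function(y, X, terms) {
  if (length(terms) == 0) return(sum((y - mean(y))^2))
  fit <- lm(y ~ ., data = X[, terms, drop = FALSE])
  sum(residuals(fit)^2)
}

#' Stepwise multiple linear regression
#'
#' Classic forward-entry/backward-removal selection: at each step the
#' candidate with the smallest partial-F p-value enters if below `pEnter`;
#' any included term whose partial-F p-value exceeds `pRemove` is then
#' removed; iteration stops when nothing changes. Coefficients are ordinary
#' least squares; R-squared is `1 - RSS/TSS` of the final model. Perfectly
#' collinear candidates (no rank increase) are skipped with a log entry.
#' The default thresholds 0.05/0.10 are the conventional stepwise defaults
#' of standard statistics packages.
#'
#' @param y numeric response (compound content).
#' @param X data.frame of candidate predictors.
#' @param pEnter entry threshold (must be <= `pRemove`).
#' @param pRemove removal threshold.
#' @param response name recorded on the returned equation.
#' @return a [RegressionEquation-class].
#' @export
#' @examples
#' x <- data.frame(a = 1:20, b = rnorm(20))
#' stepwiseRegression(2 + 3 * x$a, x)
stepwiseRegression <- function(y, X, pEnter = 0.05, pRemove = 0.10,
                               response = "y") {
  X <- as.data.frame(X)
  n <- length(y)
  if (n != nrow(X)) stop("y and X must have equal length")
  if (n <= ncol(X) + 1)
    stop("need n > number of candidate predictors + 1")
  if (pEnter > pRemove) stop("pEnter must be <= pRemove")
  if (var(y) == 0) stop("degenerate fit: constant response")
  tss <- sum((y - mean(y))^2)
  current <- character(0)
  repeat {
    changed <- FALSE
    # forward entry
    cand <- setdiff(names(X), current)
    if (length(cand)) {
      rssCur <- rssOf(y, X, current)
      ps <- vapply(cand, function(cn) {
        rssNew <- rssOf(y, X, c(current, cn))
        if (rssNew >= rssCur - 1e-12 * max(rssCur, 1)) {
          # no reduction at all can also mean perfect collinearity
          qx <- qr(cbind(1, as.matrix(X[, c(current, cn), drop = FALSE])))
          if (qx$rank < length(current) + 2) {
            logMsg("candidate '", cn, "' perfectly collinear; skipped",
                   level = "WARN")
            return(1)
          }
        }
        if (rssNew <= 0) return(0)  # exact fit
        partialFTest(rssCur, rssNew, 1, n, length(current) + 1)$p
      }, 0)
      if (min(ps) < pEnter) {
        current <- c(current, cand[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward removal
    if (length(current) > 0) {
      rssFull <- rssOf(y, X, current)
      if (rssFull > 0) {
        ps <- vapply(current, function(cn) {
          rssRed <- rssOf(y, X, setdiff(current, cn))
          partialFTest(rssRed, rssFull, 1, n, length(current))$p
        }, 0)
        if (max(ps) > pRemove) {
          current <- setdiff(current, current[which.max(ps)])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  if (length(current) == 0) {
    return(regressionEquation(response, mean(y), numeric(),
                              rSquared = 0, n = n))
  }
  fit <- lm(y ~ ., data = X[, current, drop = FALSE])
  rss <- sum(residuals(fit)^2)
  coefs <- coef(fit)[-1]
  names(coefs) <- current
  pvals <- if (rss > 0) {
    vapply(current, function(cn) {
      rssRed <- rssOf(y, X, setdiff(current, cn))
      partialFTest(rssRed, rss, 1, n, length(current))$p
    }, 0)
  } else stats::setNames(rep(0, length(current)), current)
  regressionEquation(response, unname(coef(fit)[1]), coefs,
                     rSquared = 1 - rss / tss, n = n, pValues = pvals)
}

#' Apply a regression equation to a raster stack
#'
#' Cell-wise `intercept + sum(coefficient * layer)` on jointly valid cells;
#' nodata propagates. Negative predicted contents are retained (the overlay
#' normalizes them away) but counted and logged as extrapolation flags.
#'
#' @param eq a [RegressionEquation-class].
#' @param stack an [EnvStack-class].
#' @return a [RasterGrid-class].
#' @export
#' @examples
#' eqs <- builtinEquations()
applyEquation <- function(eq, stack) {
  miss <- setdiff(names(eq@coefficients), layerNames(stack))
  if (length(miss))
    stop("equation predictor(s) missing from stack: ",
         paste(miss, collapse = ", "))
  h <- gridHeader(stack)
  vals <- matrix(eq@intercept, h@nrows, h@ncols)
  for (nm in names(eq@coefficients))
    vals <- vals + eq@coefficients[[nm]] * getLayer(stack, nm)@values
  vm <- validMask(stack)
  vals[!vm] <- NA
  nNeg <- sum(vals < 0, na.rm = TRUE)
  if (nNeg > 0)
    logMsg(nNeg, " cell(s) with negative predicted ", eq@response,
           " content (extrapolation)", level = "WARN")
  rasterGrid(h, vals)
}

#' The five published compound-content equations
#'
#' The printed stepwise-regression equations linking compound contents
#' (percent dry mass) of *G. dahurica* roots to the main ecological factors,
#' kept verbatim as reference fixtures with their printed R-squared values
#' attached. Predictors: `bio1` = annual mean temperature (deg C), `bio3` =
#' temperature seasonality (SD x 100), `bio4` = annual precipitation (mm);
#' units are a documented assumption, as the source equations are printed
#' without them.
#'
#' \itemize{
#'   \item swertiamarin `= 0.021 + 0.037 bio1 + 0.001 bio4` (R2 0.365)
#'   \item gentiopicroside `= -0.581 + 0.53 bio1 + 0.021 bio4` (R2 0.327)
#'   \item sweroside `= -0.05 + 0.000352 bio4` (R2 0.349)
#'   \item loganic acid and gentiopicroside
#'     `= 14.493 - 0.01 bio3 + 0.02 bio4` (R2 0.304)
#'   \item total iridoids `= -1.208 + 0.697 bio1 + 0.032 bio4` (R2 0.336)
#' }
#'
#' @return list of five [RegressionEquation-class] objects.
#' @export
builtinEquations <- function() {
  list(
    regressionEquation("swertiamarin", 0.021,
                       c(bio1 = 0.037, bio4 = 0.001), rSquared = 0.365),
    regressionEquation("gentiopicroside", -0.581,
                       c(bio1 = 0.53, bio4 = 0.021), rSquared = 0.327),
    regressionEquation("sweroside", -0.05,
                       c(bio4 = 0.000352), rSquared = 0.349),
    regressionEquation("loganic_acid_and_gentiopicroside", 14.493,
                       c(bio3 = -0.01, bio4 = 0.02), rSquared = 0.304),
    regressionEquation("total_iridoids", -1.208,
                       c(bio1 = 0.697, bio4 = 0.032), rSquared = 0.336)
  )
}
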