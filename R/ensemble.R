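#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, ties counted one half. Computed from
#' midranks, which is exactly the all-pairs count.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
aucScore <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run the background-resampled BRT ensemble
#'
#' For each iteration: draw a fresh background sample of size equal to the
#' presence-cell count (derived seed per iteration), build the
#' presence/background training set, select the tree count by stratified
#' 10-fold cross-validation, fit the final model, and predict the suitability
#' raster. Aggregates the cell-wise mean and population standard deviation of
#' suitability, the per-iteration held-out AUC, and the per-iteration
#' relative contributions (averaged, then renormalized to 100).
#' Iterations whose fit fails are skipped and logged; more than 10% failures
#' aborts the ensemble.
#'
#' @param presence a [PresenceGrid-class].
#' @param stack an [EnvStack-class].
#' @param rule a [ScreeningRule-class] for background eligibility.
#' @param config a [FitConfig-class].
#' @param nIterations number of background redraws (default 200, the
#'   published ensemble size).
#' @param seed master seed; per-iteration streams are derived from it.
#' @return an [EnsembleSummary-class].
#' @export
runEnsemble <- function(presence, stack, rule, config = fitConfig(),
                        nIterations = 200, seed = 1) {
  if (nPresence(presence) == 0) stop("presence grid is empty")
  eligible <- screenBackgroundMask(stack, rule)
  n <- nPresence(presence)
  h <- gridHeader(stack)
  vm <- validMask(stack)
  sumP <- matrix(0, h@nrows, h@ncols)
  sumP2 <- matrix(0, h@nrows, h@ncols)
  rcAll <- NULL
  aucs <- numeric(0)
  nTreesSel <- integer(0)
  nFailed <- 0L
  for (i in seq_len(nIterations)) {
    res <- tryCatch({
      bg <- sampleBackgroundPoints(eligible, n, presence,
                                   splitSeed(seed, 1000 + i))
      training <- buildTrainingSet(presence, bg, stack)
      cfg <- config
      cfg@seed <- splitSeed(seed, 2000 + i)
      cv <- cvSelectTrees(training, cfg)
      nOpt <- max(cv$nTreesOptimal, cfg@stepSize)
      model <- fitBRT(training, cfg, nOpt)
      pred <- predictBRT(model, stack)
      list(pred = pred, rc = relativeInfluence(model), auc = cv$cvAUC,
           nOpt = nOpt)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      nFailed <- nFailed + 1L
      logMsg("iteration ", i, " failed: ", conditionMessage(res),
             level = "WARN")
      next
    }
    pv <- res$pred@values
    pv[res$pred@mask] <- 0
    sumP <- sumP + pv
    sumP2 <- sumP2 + pv^2
    rcAll <- rbind(rcAll, res$rc)
    aucs <- c(aucs, res$auc)
    nTreesSel <- c(nTreesSel, res$nOpt)
  }
  nOk <- nIterations - nFailed
  if (nFailed > 0.1 * nIterations)
    stop("ensemble failed: ", nFailed, " of ", nIterations,
         " iterations errored")
  meanP <- sumP / nOk
  varP <- pmax(sumP2 / nOk - meanP^2, 0)  # population variance
  meanP[!vm] <- NA; varP[!vm] <- NA
  rcMean <- colMeans(rcAll)
  rcMean <- 100 * rcMean / sum(rcMean)
  rcSd <- apply(rcAll, 2, stats::sd)
  new("EnsembleSummary",
      meanSuitability = rasterGrid(h, meanP),
      sdSuitability = rasterGrid(h, sqrt(varP)),
      rcTable = data.frame(predictor = names(rcMean), mean = unname(rcMean),
                           sd = unname(rcSd), stringsAsFactors = FALSE),
      aucPerIteration = aucs, nTreesPerIteration = nTreesSel,
      nIterations = as.integer(nOk), nFailed = nFailed)
}

#' Main-factor selection result
#'
#' @slot selected data.frame `predictor`, `rc`, descending RC, all above the
#'   threshold.
#' @slot cumulativeRC sum of the selected RC values (%).
#' @slot rcThreshold the selection threshold (%).
#' @slot criterionMet `TRUE` when the cumulative RC exceeds 95%, the
#'   main-factor criterion.
#' @export
setClass("MainFactorSelection", representation(
  selected = "data.frame", cumulativeRC = "numeric",
  rcThreshold = "numeric", criterionMet = "logical"
))

setMethod("show", "MainFactorSelection", function(object) {
  cat(sprintf("MainFactorSelection: %d factors with RC > %g%%, cumulative %.3f%%%s\n",
              nrow(object@selected), object@rcThreshold,
              object@cumulativeRC,
              if (object@criterionMet) " (> 95% criterion met)" else ""))
  for (i in seq_len(nrow(object@selected)))
    cat(sprintf("  %-12s %7.3f%%\n", object@selected$predictor[i],
                object@selected$rc[i]))
})

#' Select the main ecological factors by relative contribution
#'
#' Keeps the predictors whose RC strictly exceeds the threshold (default 2%),
#' sorted descending, and reports their cumulative RC. The selection is
#' flagged when the cumulative RC exceeds 95%, the criterion used to call a
#' set of predictors the main ecological factors.
#'
#' @param rc named numeric vector of RC percentages, or the `rcTable` of an
#'   [EnsembleSummary-class].
#' @param rcThreshold selection threshold (%).
#' @return a [MainFactorSelection-class].
#' @export
#' @examples
#' selectMainFactors(referenceRCTable()$rc |> setNames(referenceRCTable()$predictor))
selectMainFactors <- function(rc, rcThreshold = 2.0) {
  if (is.data.frame(rc)) rc <- stats::setNames(rc$mean, rc$predictor)
  if (length(rc) == 0) stop("empty RC table")
  if (any(rc < 0)) stop("RC values must be non-negative")
  sel <- sort(rc[rc > rcThreshold], decreasing = TRUE)
  cum <- if (length(sel)) sum(sel) else 0
  new("MainFactorSelection",
      selected = data.frame(predictor = names(sel), rc = unname(sel),
                            stringsAsFactors = FALSE),
      cumulativeRC = cum, rcThreshold = rcThreshold,
      criterionMet = cum > 95)
}

#' Sum relative contributions by factor group
#'
#' @param rc named numeric vector of RC percentages (or an `rcTable`
#'   data.frame).
#' @param groups named character vector mapping every predictor to a group
#'   name.
#' @return named numeric vector of per-group RC sums.
#' @export
#' @examples
#' tab <- referenceRCTable()
#' groupRC(setNames(tab$rc, tab$predictor), setNames(tab$group, tab$predictor))
groupRC <- function(rc, groups) {
  if (is.data.frame(rc)) rc <- stats::setNames(rc$mean, rc$predictor)
  un <- setdiff(names(rc), names(groups))
  if (length(un))
    stop("predictor(s) not assigned to a group: ", paste(un, collapse = ", "))
  s <- tapply(rc, groups[names(rc)], sum)
  stats::setNames(as.numeric(s), names(s))
}

#' Published relative contributions of the 15 ecological predictors
#'
#' The RC percentages reported for the 15 ecological factors used to model
#' *Gentiana dahurica* distribution (five bioclimatic variables, solar
#' radiation, elevation, vegetation type, six soil variables and annual
#' sunshine duration), with each factor's group. These printed values serve
#' as a reference input for the selection and grouping operations; note the
#' published column sums to 100.001 due to rounding.
#'
#' @return data.frame `predictor`, `rc` (%), `group`, `kind`.
#' @export
referenceRCTable <- function() {
  data.frame(
    predictor = c("BIO1", "BIO2", "BIO3", "BIO4", "BIO5", "Srad", "Elev",
                  "Zblx", "SOI1", "SOI2", "SOI3", "SOI4", "SOI5", "SOI6",
                  "Suntime"),
    rc = c(4.577, 0.539, 10.091, 14.567, 0.577, 1.026, 30.188,
           5.071, 1.652, 0.019, 0.004, 28.974, 0.148, 0.091, 2.477),
    group = c(rep("climatic", 5), "sun_radiation", "terrain", "vegetation",
              rep("soil", 6), "climatic"),
    kind = c(rep("continuous", 7), "categorical", "continuous",
             "categorical", "continuous", "categorical", "continuous",
             "continuous", "continuous"),
    stringsAsFactors = FALSE)
}
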