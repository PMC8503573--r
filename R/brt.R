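## Gradient boosting with Bernoulli deviance for presence/background data.
## Trees are grown by the compiled greedy splitter (src/brt_tree.cpp);
## terminal values are one-step Newton estimates over the in-bag rows of
## each leaf, clamped to |value| <= 10 to guard separable leaves.

# Split a feature table into the pieces the boosting loop needs.
featureParts <- function(data) {
  if (!"label" %in% names(data)) stop("feature table must have a 'label' column")
  preds <- setdiff(names(data), "label")
  kinds <- attr(data, "kinds")
  if (is.null(kinds)) kinds <- stats::setNames(rep("continuous", length(preds)), preds)
  X <- as.matrix(data[, preds, drop = FALSE])
  storage.mode(X) <- "double"
  list(X = X, y = as.numeric(data$label), preds = preds,
       isCat = unname(kinds[preds] == "categorical"),
       kinds = kinds[preds])
}

# A booster is an environment so cross-validation can grow fold models
# incrementally while tracking held-out scores. Each booster owns a private
# RNG stream (swapped in and out around every growth step).
newBooster <- function(X, y, isCat, config, seed, Xheld = NULL) {
  b <- new.env(parent = emptyenv())
  b$X <- X; b$y <- y; b$isCat <- isCat; b$config <- config
  p0 <- mean(y)
  b$init <- log(p0 / (1 - p0))
  b$score <- rep(b$init, length(y))
  b$trees <- list()
  b$Xheld <- Xheld
  if (!is.null(Xheld)) b$heldScore <- rep(b$init, nrow(Xheld))
  b$rng <- withSeed(seed, get(".Random.seed", envir = globalenv()))
  b
}

growTrees <- function(b, k) {
  cfg <- b$config
  n <- length(b$y)
  nBag <- max(1L, floor(cfg@bagFraction * n))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", b$rng, envir = globalenv())
  on.exit({
    b$rng <- get(".Random.seed", envir = globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  for (t in seq_len(k)) {
    p <- plogis(b$score)
    z <- b$y - p
    w <- p * (1 - p)
    bag <- if (nBag == n) seq_len(n) else sample.int(n, nBag)
    tr <- cpp_grow_tree(b$X, b$isCat, z, bag - 1L, cfg@treeComplexity,
                        cfg@minObs)
    nNodes <- length(tr$var)
    leafValue <- rep(NA_real_, nNodes)
    for (nd in which(tr$var == 0L)) {
      idx <- bag[tr$inbagNode == nd]
      denom <- sum(w[idx])
      val <- if (denom < 1e-8) 0 else sum(z[idx]) / denom
      leafValue[nd] <- max(-10, min(10, val))
    }
    tree <- list(var = tr$var, thr = tr$thr, catLeft = tr$catLeft,
                 catRight = tr$catRight, left = tr$left, right = tr$right,
                 improvement = tr$improvement, n = tr$n,
                 leafValue = leafValue)
    asg <- cpp_tree_assign(b$X, tree$var, tree$thr, tree$catLeft,
                           tree$catRight, tree$left, tree$right, tree$n)
    b$score <- b$score + cfg@learningRate * leafValue[asg$node]
    if (!is.null(b$Xheld)) {
      ah <- cpp_tree_assign(b$Xheld, tree$var, tree$thr, tree$catLeft,
                            tree$catRight, tree$left, tree$right, tree$n)
      b$heldScore <- b$heldScore + cfg@learningRate * leafValue[ah$node]
    }
    b$trees[[length(b$trees) + 1L]] <- tree
  }
  invisible(b)
}

#' Fit a boosted regression trees model
#'
#' Bernoulli-deviance gradient boosting: the initial score is the log-odds of
#' the label prevalence; each iteration draws a `bagFraction` subsample
#' without replacement, computes pseudo-residuals `y - p`, grows a tree with
#' at most `treeComplexity` splits greedily maximizing squared-error
#' improvement, sets each terminal value by a one-step Newton update
#' `sum(residual) / sum(p(1-p))` over the in-bag rows in that leaf (clamped
#' to `[-10, 10]`), and adds `learningRate` times the tree to the score.
#' Refitting with the same seed is bit-identical.
#'
#' @param data feature table from [buildTrainingSet] or [extractFeatures]
#'   (predictor columns, `label` column, `kinds` attribute).
#' @param config a [FitConfig-class].
#' @param nTrees number of boosting iterations (use [cvSelectTrees] to choose
#'   it).
#' @return a [BoostedTreesModel-class].
#' @export
fitBRT <- function(data, config = fitConfig(), nTrees) {
  validObject(config)
  if (nTrees < 1) stop("nTrees must be >= 1")
  fp <- featureParts(data)
  if (length(unique(fp$y)) < 2)
    stop("degenerate fit: training labels are single-class")
  b <- newBooster(fp$X, fp$y, fp$isCat, config, splitSeed(config@seed, 301))
  growTrees(b, nTrees)
  new("BoostedTreesModel", initialScore = b$init, trees = b$trees,
      learningRate = config@learningRate,
      treeComplexity = config@treeComplexity,
      bagFraction = config@bagFraction, nTreesUsed = as.integer(nTrees),
      predictors = fp$preds, kinds = fp$kinds, nTrain = length(fp$y))
}

# Raw additive score (log-odds) for a predictor matrix.
brtScore <- function(model, X, nTrees = model@nTreesUsed) {
  score <- rep(model@initialScore, nrow(X))
  unseen <- 0L
  for (tree in model@trees[seq_len(nTrees)]) {
    asg <- cpp_tree_assign(X, tree$var, tree$thr, tree$catLeft,
                           tree$catRight, tree$left, tree$right, tree$n)
    score <- score + model@learningRate * tree$leafValue[asg$node]
    unseen <- unseen + asg$unseen
  }
  attr(score, "unseen") <- unseen
  score
}

modelMatrixFrom <- function(model, newdata) {
  missing <- setdiff(model@predictors, names(newdata))
  if (length(missing))
    stop("predictor(s) missing from newdata: ", paste(missing, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[, model@predictors, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Predict presence probability
#'
#' Probability is the logistic of
#' `initialScore + learningRate * sum(tree outputs)` over the first
#' `nTreesUsed` trees. For an [EnvStack-class] the prediction is evaluated on
#' jointly valid cells and returned as a raster with nodata propagated.
#' Categorical codes unseen in training are routed to the child with more
#' training weight; their count is logged and attached as attribute
#' `"unseen"`.
#'
#' @param model a [BoostedTreesModel-class].
#' @param newdata a data.frame of predictor columns, or an
#'   [EnvStack-class].
#' @param ... unused.
#' @return numeric vector of probabilities in `(0, 1)`, or a
#'   [RasterGrid-class].
#' @export
setGeneric("predictBRT", function(model, newdata, ...)
  standardGeneric("predictBRT"))

#' @rdname predictBRT
#' @export
setMethod("predictBRT", signature("BoostedTreesModel", "data.frame"),
  function(model, newdata, ...) {
    score <- brtScore(model, modelMatrixFrom(model, newdata))
    if (attr(score, "unseen") > 0)
      logMsg(attr(score, "unseen"),
             " unseen categorical code(s) routed by training weight",
             level = "WARN")
    p <- plogis(as.numeric(score))
    attr(p, "unseen") <- attr(score, "unseen")
    p
  })

#' @rdname predictBRT
#' @export
setMethod("predictBRT", signature("BoostedTreesModel", "EnvStack"),
  function(model, newdata, ...) {
    vm <- validMask(newdata)
    cells <- which(vm, arr.ind = TRUE)
    df <- as.data.frame(matrix(
      vapply(model@predictors, function(nm)
        getLayer(newdata, nm)@values[cells], numeric(nrow(cells))),
      nrow = nrow(cells), dimnames = list(NULL, model@predictors)))
    p <- predictBRT(model, df)
    vals <- matrix(NA_real_, nrow(vm), ncol(vm))
    vals[cells] <- p
    out <- rasterGrid(gridHeader(newdata), vals)
    out
  })

#' Select the number of trees by cross-validation
#'
#' Grows all folds' models in increments of `stepSize` trees, tracking the
#' pooled held-out Bernoulli deviance after each step, and stops once the
#' deviance has not improved for `patience` consecutive steps (or at
#' `maxTrees`). Folds are stratified by label and assigned by a seeded
#' permutation. Returns the tree count minimizing held-out deviance, the
#' deviance curve, and the mean per-fold held-out AUC at that optimum.
#'
#' @param data feature table with both classes.
#' @param config a [FitConfig-class].
#' @return list with `nTreesOptimal`, `cvDevianceCurve` (data.frame `trees`,
#'   `deviance`), `cvAUC` (mean held-out AUC), `foldAUC` (per-fold values).
#' @export
cvSelectTrees <- function(data, config = fitConfig()) {
  validObject(config)
  fp <- featureParts(data)
  n <- length(fp$y)
  if (n < 2 * config@nFolds) stop("need at least 2 rows per fold")
  folds <- makeStratifiedFolds(fp$y, config@nFolds,
                               splitSeed(config@seed, 101))
  boosters <- lapply(seq_len(config@nFolds), function(f) {
    tr <- which(folds != f)
    newBooster(fp$X[tr, , drop = FALSE], fp$y[tr], fp$isCat, config,
               splitSeed(config@seed, 200 + f),
               Xheld = fp$X[folds == f, , drop = FALSE])
  })
  maxSteps <- max(1L, config@maxTrees %/% config@stepSize)
  devCurve <- numeric(0)
  bestDev <- Inf; bestStep <- 0L; sinceBest <- 0L
  bestHeld <- rep(NA_real_, n)
  heldNow <- rep(NA_real_, n)
  for (s in seq_len(maxSteps)) {
    for (f in seq_len(config@nFolds)) {
      growTrees(boosters[[f]], config@stepSize)
      heldNow[folds == f] <- boosters[[f]]$heldScore
    }
    dev <- bernoulliDeviance(fp$y, plogis(heldNow))
    devCurve[s] <- dev
    if (dev < bestDev - 1e-12) {
      bestDev <- dev; bestStep <- s; sinceBest <- 0L
      bestHeld <- heldNow
    } else sinceBest <- sinceBest + 1L
    if (sinceBest >= config@patience) break
  }
  foldAUC <- vapply(seq_len(config@nFolds), function(f) {
    idx <- folds == f
    aucScore(plogis(bestHeld[idx]), fp$y[idx])
  }, 0)
  list(nTreesOptimal = bestStep * config@stepSize,
       cvDevianceCurve = data.frame(
         trees = seq_along(devCurve) * config@stepSize,
         deviance = devCurve),
       cvAUC = mean(foldAUC), foldAUC = foldAUC)
}

# Stratified fold assignment via seeded permutation; retries with a derived
# seed if some fold ends up single-class, then errors.
makeStratifiedFolds <- function(y, nFolds, seed) {
  for (attempt in 0:2) {
    folds <- integer(length(y))
    withSeed(splitSeed(seed, attempt), {
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        folds[idx] <- rep_len(seq_len(nFolds), length(idx))
      }
    })
    ok <- all(vapply(seq_len(nFolds), function(f)
      length(unique(y[folds == f])) == 2, TRUE))
    if (ok) return(folds)
  }
  stop("could not build stratified folds with both classes in every fold")
}

#' Relative influence of each predictor
#'
#' The relative contribution (RC) of a predictor is the sum of the
#' squared-error improvements of all splits on it over the first
#' `nTrees` trees, normalized so the total is 100. Predictors never split on
#' get 0.
#'
#' @param model a [BoostedTreesModel-class].
#' @param nTrees number of leading trees to use (default `nTreesUsed`).
#' @return named numeric vector of percentages summing to 100.
#' @export
relativeInfluence <- function(model, nTrees = model@nTreesUsed) {
  tot <- stats::setNames(numeric(length(model@predictors)), model@predictors)
  for (tree in model@trees[seq_len(nTrees)]) {
    sp <- tree$var > 0L
    if (any(sp)) {
      s <- tapply(tree$improvement[sp], model@predictors[tree$var[sp]], sum)
      tot[names(s)] <- tot[names(s)] + s
    }
  }
  if (sum(tot) <= 0)
    stop("relative influence undefined: model has no splits")
  100 * tot / sum(tot)
}

#' Partial dependence (marginal effect) curve
#'
#' For each grid value `v` of the chosen predictor (an evenly spaced
#' quantile grid for continuous predictors; the observed codes for
#' categorical ones), every data row has the predictor forced to `v` and the
#' mean predicted probability is recorded.
#'
#' @param model a [BoostedTreesModel-class].
#' @param predictor predictor name.
#' @param data feature table providing the averaging distribution.
#' @param nPoints grid size for continuous predictors.
#' @return data.frame `value`, `response` (probability scale).
#' @export
partialDependence <- function(model, predictor, data, nPoints = 25) {
  if (!predictor %in% model@predictors)
    stop("predictor '", predictor, "' not in the model")
  if (nrow(data) == 0) stop("empty data")
  x <- data[[predictor]]
  grid <- if (identical(unname(model@kinds[predictor]), "categorical"))
    sort(unique(x))
  else unique(quantile(x, probs = seq(0, 1, length.out = nPoints),
                       names = FALSE, type = 7))
  resp <- vapply(grid, function(v) {
    d <- data
    d[[predictor]] <- v
    mean(predictBRT(model, d[, model@predictors, drop = FALSE]))
  }, 0)
  data.frame(value = grid, response = resp)
}

#' Serialize a model to JSON and back
#'
#' The JSON layout has a `header` (fit settings, predictor names and kinds)
#' and a `body` (the tree list as flat node arrays). Round-tripping preserves
#' predictions exactly.
#'
#' @param model a [BoostedTreesModel-class].
#' @param path file path.
#' @return [readBRTModel] returns the model; [writeBRTModel] the path,
#'   invisibly.
#' @export
writeBRTModel <- function(model, path) {
  obj <- list(
    header = list(initialScore = model@initialScore,
                  learningRate = model@learningRate,
                  treeComplexity = model@treeComplexity,
                  bagFraction = model@bagFraction,
                  nTreesUsed = model@nTreesUsed,
                  predictors = model@predictors,
                  kinds = as.list(model@kinds), nTrain = model@nTrain),
    body = lapply(model@trees, function(tr)
      list(var = tr$var, thr = tr$thr, catLeft = tr$catLeft,
           catRight = tr$catRight, left = tr$left, right = tr$right,
           improvement = tr$improvement, n = tr$n,
           leafValue = tr$leafValue)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname writeBRTModel
#' @export
readBRTModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  h <- obj$header
  trees <- lapply(obj$body, function(tr) {
    list(var = as.integer(tr$var), thr = as.numeric(tr$thr),
         catLeft = lapply(tr$catLeft, as.numeric),
         catRight = lapply(tr$catRight, as.numeric),
         left = as.integer(tr$left), right = as.integer(tr$right),
         improvement = as.numeric(tr$improvement), n = as.integer(tr$n),
         leafValue = as.numeric(tr$leafValue))
  })
  new("BoostedTreesModel", initialScore = h$initialScore,
      trees = trees, learningRate = h$learningRate,
      treeComplexity = as.integer(h$treeComplexity),
      bagFraction = h$bagFraction, nTreesUsed = as.integer(h$nTreesUsed),
      predictors = as.character(h$predictors),
      kinds = unlist(h$kinds), nTrain = as.integer(h$nTrain))
}
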