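test_that("fitBRT is deterministic and rejects degenerate inputs", {
  d <- signalData(120, seed = 1)
  cfg <- fastConfig(seed = 3)
  m1 <- fitBRT(d, cfg, 30)
  m2 <- fitBRT(d, cfg, 30)
  expect_identical(m1@trees, m2@trees)
  expect_equal(m1@initialScore, log(mean(d$label) / (1 - mean(d$label))))

  d0 <- d; d0$label <- 1L
  expect_error(fitBRT(d0, cfg, 10), "single-class")
  expect_error(fitConfig(learningRate = 0), "learningRate")
})

test_that("no-signal labels give prevalence-level predictions", {
  withr::with_seed(5, {
    d <- data.frame(x1 = rnorm(300), x2 = rnorm(300),
                    label = rbinom(300, 1, 0.4))
  })
  attr(d, "kinds") <- c(x1 = "continuous", x2 = "continuous")
  cfg <- fastConfig(seed = 11)
  m <- fitBRT(d, cfg, 50)
  p <- predictBRT(m, d[, 1:2])
  expect_lt(abs(mean(p) - mean(d$label)), 0.05)
  cv <- cvSelectTrees(d, cfg)
  expect_gt(cv$cvAUC, 0.3)
  expect_lt(cv$cvAUC, 0.7)
})

test_that("a perfectly separating predictor reaches training AUC 1", {
  withr::with_seed(8, {
    x <- rep(c(0, 1), each = 100)
    d <- data.frame(xbin = x, noise = rnorm(200), label = as.integer(x))
  })
  attr(d, "kinds") <- c(xbin = "continuous", noise = "continuous")
  m <- fitBRT(d, fitConfig(treeComplexity = 1, maxTrees = 2000, seed = 4),
              2000)
  p <- predictBRT(m, d[, 1:2])
  expect_equal(aucScore(p, d$label), 1.0)
})

test_that("prediction is the logistic of the additive tree score", {
  d <- signalData(150, seed = 2)
  cfg <- fastConfig(seed = 6)
  m <- fitBRT(d, cfg, 20)
  # zero trees -> constant prevalence
  m0 <- m; m0@nTreesUsed <- 0L
  p0 <- predictBRT(m0, d[, 1:3])
  expect_true(all(abs(p0 - mean(d$label)) < 1e-12))
  # probabilities strictly inside (0,1)
  p <- predictBRT(m, d[, 1:3])
  expect_true(all(p > 0 & p < 1))
  # missing predictor errors
  expect_error(predictBRT(m, d[, 2:3, drop = FALSE]), "missing")
})

test_that("scores agree with an independent gradient-boosting oracle", {
  library(xgboost)
  d <- signalData(500, seed = 10)
  test <- signalData(500, seed = 20)
  X <- as.matrix(d[, 1:3]); Xt <- as.matrix(test[, 1:3])
  cfg <- fitConfig(treeComplexity = 3, learningRate = 0.1, bagFraction = 1,
                   maxTrees = 150, minObs = 5, seed = 2)
  mine <- fitBRT(d, cfg, 150)
  aucMine <- aucScore(predictBRT(mine, test[, 1:3]), test$label)
  dm <- xgboost::xgb.DMatrix(X, label = d$label, nthread = 1)
  ref <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 2, eta = 0.1,
                  nthread = 1),
    data = dm, nrounds = 150, verbose = 0)
  aucRef <- aucScore(predict(ref, xgboost::xgb.DMatrix(Xt, nthread = 1)),
                     test$label)
  expect_lt(abs(aucMine - aucRef), 0.02)
})

test_that("cross-validated tree selection behaves on signal and noise", {
  d <- signalData(200, seed = 3, beta = c(6, 0))
  cfg <- fastConfig(seed = 5)
  cv <- cvSelectTrees(d, cfg)
  expect_equal(cv$nTreesOptimal %% cfg@stepSize, 0)
  expect_gte(cv$cvAUC, 0.95)
  expect_equal(nrow(cv$cvDevianceCurve), length(cv$cvDevianceCurve$deviance))

  withr::with_seed(7, {
    dn <- data.frame(x1 = rnorm(200), x2 = rnorm(200),
                     label = rbinom(200, 1, 0.5))
  })
  attr(dn, "kinds") <- c(x1 = "continuous", x2 = "continuous")
  cvn <- cvSelectTrees(dn, fastConfig(seed = 8))
  expect_lte(cvn$nTreesOptimal, 5 * cfg@stepSize)
  expect_gt(cvn$cvAUC, 0.3)
  expect_lt(cvn$cvAUC, 0.7)
})

test_that("training deviance decreases as trees accumulate", {
  d <- signalData(200, seed = 14)
  cfg <- fitConfig(learningRate = 0.05, bagFraction = 1, minObs = 5,
                   seed = 9, maxTrees = 80)
  m <- fitBRT(d, cfg, 80)
  dev <- vapply(c(1L, 20L, 40L, 80L), function(k) {
    mk <- m; mk@nTreesUsed <- k
    p <- predictBRT(mk, d[, 1:3])
    -2 * mean(d$label * log(p) + (1 - d$label) * log(1 - p))
  }, 0)
  expect_true(all(diff(dev) < 0))
})

test_that("relative influence normalizes to 100 and is concentrated correctly", {
  # single active predictor takes all influence
  withr::with_seed(4, {
    d <- data.frame(x1 = rnorm(200), x2 = rnorm(200))
  })
  d$label <- as.integer(d$x1 > 0)
  attr(d, "kinds") <- c(x1 = "continuous", x2 = "continuous")
  m <- fitBRT(d, fitConfig(treeComplexity = 1, learningRate = 0.2,
                           minObs = 5, seed = 2), 20)
  ri <- relativeInfluence(m)
  expect_equal(sum(ri), 100, tolerance = 1e-9)
  expect_equal(unname(ri["x1"]), 100, tolerance = 1e-9)
  expect_equal(unname(ri["x2"]), 0)
})

test_that("a 4x stronger predictor out-ranks the weaker one almost always", {
  wins <- vapply(1:20, function(rep) {
    withr::with_seed(300 + rep, {
      xA <- rnorm(250); xB <- rnorm(250)
      lab <- rbinom(250, 1, plogis(2 * xA + 0.5 * xB))
      d <- data.frame(xA = xA, xB = xB, label = lab)
    })
    attr(d, "kinds") <- c(xA = "continuous", xB = "continuous")
    m <- fitBRT(d, fastConfig(seed = rep), 60)
    ri <- relativeInfluence(m)
    ri["xA"] > ri["xB"]
  }, TRUE)
  expect_gte(sum(wins), 18)
})

test_that("partial dependence equals brute-force forcing", {
  d <- signalData(150, seed = 6)
  m <- fitBRT(d, fastConfig(seed = 7), 15)
  pd <- partialDependence(m, "x1", d, nPoints = 9)
  # brute force: force each row one at a time
  for (i in seq_len(nrow(pd))) {
    preds <- vapply(seq_len(nrow(d)), function(r) {
      row <- d[r, 1:3, drop = FALSE]
      row$x1 <- pd$value[i]
      predictBRT(m, row)[1]
    }, 0)
    expect_equal(pd$response[i], mean(preds), tolerance = 1e-12)
  }
  expect_true(all(pd$response > 0 & pd$response < 1))
})

test_that("partial dependence on an unsplit predictor is flat", {
  withr::with_seed(9, {
    d <- data.frame(x1 = rnorm(120), x3 = rnorm(120))
  })
  d$label <- as.integer(d$x1 > 0)  # perfectly separable on x1 alone
  attr(d, "kinds") <- c(x1 = "continuous", x3 = "continuous")
  m <- fitBRT(d, fitConfig(treeComplexity = 1, learningRate = 0.1,
                           bagFraction = 1, minObs = 5, seed = 3), 25)
  ri <- relativeInfluence(m)
  expect_equal(unname(ri["x3"]), 0)
  pd <- partialDependence(m, "x3", d, nPoints = 5)
  expect_true(all(abs(pd$response - pd$response[1]) < 1e-12))
})

test_that("single-split trees give two-level step partial dependence", {
  withr::with_seed(12, {
    d <- data.frame(x1 = runif(100), label = rbinom(100, 1, 0.5))
  })
  d$label <- as.integer(d$x1 > 0.5)
  attr(d, "kinds") <- c(x1 = "continuous")
  m <- fitBRT(d, fitConfig(treeComplexity = 1, learningRate = 0.3,
                           bagFraction = 1, minObs = 5, seed = 1), 1)
  tree <- m@trees[[1]]
  thr <- tree$thr[1]
  pd <- partialDependence(m, "x1", d, nPoints = 25)
  expect_equal(length(unique(round(pd$response, 12))), 2)
  expect_lt(max(pd$response[pd$value < thr]),
            min(pd$response[pd$value > thr]))
})

test_that("categorical splits honor subsets and route unseen codes", {
  withr::with_seed(15, {
    code <- sample(1:4, 300, replace = TRUE)
    lab <- as.integer(code %in% c(2, 4))
    d <- data.frame(soil = code, label = lab)
  })
  attr(d, "kinds") <- c(soil = "categorical")
  m <- fitBRT(d, fitConfig(treeComplexity = 1, learningRate = 0.3,
                           bagFraction = 1, minObs = 5, seed = 2), 40)
  p <- predictBRT(m, d[, "soil", drop = FALSE])
  expect_equal(aucScore(p, d$label), 1.0)
  # unseen code routes deterministically with a logged count
  msgs <- capture_messages(
    pu <- predictBRT(m, data.frame(soil = 99)))
  expect_match(paste(msgs, collapse = " "), "unseen")
  expect_equal(attr(pu, "unseen"), m@nTreesUsed)
  expect_true(pu[1] > 0 && pu[1] < 1)
})

test_that("models survive a JSON round trip with identical predictions", {
  sc <- demoScene(seed = 2, ncols = 12, nrows = 12, nOccurrences = 60,
                  nPresence = 25)
  el <- screenBackgroundMask(sc$stack, sc$rule)
  bg <- sampleBackgroundPoints(el, 25, sc$presence, seed = 3)
  tr <- buildTrainingSet(sc$presence, bg, sc$stack)
  m <- fitBRT(tr, fastConfig(seed = 5), 25)
  f <- withr::local_tempfile(fileext = ".json")
  writeBRTModel(m, f)
  m2 <- readBRTModel(f)
  expect_equal(predictBRT(m2, tr[, m@predictors]),
               predictBRT(m, tr[, m@predictors]))
  expect_equal(relativeInfluence(m2), relativeInfluence(m))
})
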