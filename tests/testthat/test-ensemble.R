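test_that("aucScore matches brute-force pair counting", {
  expect_equal(aucScore(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(aucScore(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(aucScore(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_error(aucScore(1:3, c(1, 1, 1)), "both classes")
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(10:500, 1)
      s <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # plenty of ties
      l <- rbinom(n, 1, 0.5)
      if (length(unique(l)) < 2) l[1:2] <- c(0, 1)
      expect_equal(aucScore(s, l), bruteAUC(s, l))
    }
  })
})

test_that("auc complement identity holds for tie-free scores", {
  withr::with_seed(22, {
    s <- runif(60)
    l <- rbinom(60, 1, 0.5); l[1:2] <- c(0, 1)
  })
  expect_equal(aucScore(s, l) + aucScore(s, 1 - l), 1)
})

test_that("a small ensemble aggregates mean, SD, RC and AUC coherently", {
  sc <- demoScene(seed = 5, ncols = 20, nrows = 20, nOccurrences = 120,
                  nPresence = 40)
  cfg <- fastConfig(seed = 1, nFolds = 5)
  ens <- suppressMessages(
    runEnsemble(sc$presence, sc$stack, sc$rule, cfg, nIterations = 3,
                seed = 77))
  expect_equal(ens@nIterations, 3L)
  expect_equal(length(ens@aucPerIteration), 3)
  expect_equal(sum(ens@rcTable$mean), 100, tolerance = 0.01)
  vm <- validMask(sc$stack)
  mu <- ens@meanSuitability@values[vm]
  expect_true(all(mu >= 0 & mu <= 1))
  expect_true(all(ens@sdSuitability@values[vm] >= 0))
  # determinism of the whole ensemble
  ens2 <- suppressMessages(
    runEnsemble(sc$presence, sc$stack, sc$rule, cfg, nIterations = 3,
                seed = 77))
  expect_equal(ens2@meanSuitability@values, ens@meanSuitability@values)
  expect_equal(ens2@aucPerIteration, ens@aucPerIteration)
})

test_that("mean and SD follow their definitions for two iterations", {
  sc <- demoScene(seed = 8, ncols = 16, nrows = 16, nOccurrences = 80,
                  nPresence = 30)
  cfg <- fastConfig(seed = 2, nFolds = 5, maxTrees = 60)
  el <- screenBackgroundMask(sc$stack, sc$rule)
  preds <- lapply(1:2, function(i) {
    bg <- sampleBackgroundPoints(el, 30, sc$presence, splitSeed(99, 1000 + i))
    tr <- buildTrainingSet(sc$presence, bg, sc$stack)
    ci <- cfg; ci@seed <- splitSeed(99, 2000 + i)
    cv <- cvSelectTrees(tr, ci)
    m <- fitBRT(tr, ci, max(cv$nTreesOptimal, ci@stepSize))
    predictBRT(m, sc$stack)@values
  })
  ens <- suppressMessages(
    runEnsemble(sc$presence, sc$stack, sc$rule, cfg, nIterations = 2,
                seed = 99))
  manualMean <- (preds[[1]] + preds[[2]]) / 2
  manualSd <- sqrt(((preds[[1]] - manualMean)^2 +
                      (preds[[2]] - manualMean)^2) / 2)
  vm <- validMask(sc$stack)
  expect_equal(ens@meanSuitability@values[vm], manualMean[vm],
               tolerance = 1e-12)
  expect_equal(ens@sdSuitability@values[vm], manualSd[vm], tolerance = 1e-10)
})

test_that("main-factor selection reproduces the published seven-factor set", {
  tab <- referenceRCTable()
  rc <- setNames(tab$rc, tab$predictor)
  sel <- selectMainFactors(rc)
  expect_equal(nrow(sel@selected), 7)
  expect_equal(sel@selected$predictor,
               c("Elev", "SOI4", "BIO4", "BIO3", "Zblx", "BIO1", "Suntime"))
  expect_equal(sel@cumulativeRC, 95.945, tolerance = 1e-9)
  expect_true(sel@criterionMet)
  # threshold 0 selects everything; the printed column sums to 100.001
  sel0 <- selectMainFactors(rc, 0)
  expect_equal(nrow(sel0@selected), 15)
  expect_equal(sel0@cumulativeRC, 100.001, tolerance = 1e-9)
  # nothing above threshold
  selNone <- selectMainFactors(c(a = 1, b = 0.5), 2)
  expect_equal(nrow(selNone@selected), 0)
  expect_equal(selNone@cumulativeRC, 0)
})

test_that("grouped RC sums conserve the published totals", {
  tab <- referenceRCTable()
  rc <- setNames(tab$rc, tab$predictor)
  groups <- setNames(tab$group, tab$predictor)
  g <- groupRC(rc, groups)
  expect_equal(unname(g["climatic"]), 32.828, tolerance = 1e-9)
  expect_equal(unname(g["soil"]), 30.888, tolerance = 1e-9)
  expect_equal(sum(g), 100.001, tolerance = 1e-9)
  # identity mapping
  gid <- groupRC(c(a = 5, b = 7), c(a = "a", b = "b"))
  expect_equal(unname(gid[c("a", "b")]), c(5, 7))
  expect_error(groupRC(c(a = 5, b = 7), c(a = "g")), "not assigned")
})

test_that("truth-active predictors out-rank the inert layer", {
  wins <- 0L
  for (rep in 1:5) {
    sc <- demoScene(seed = 400 + rep, ncols = 16, nrows = 16,
                    nOccurrences = 90, nPresence = 35)
    el <- screenBackgroundMask(sc$stack, sc$rule)
    bg <- sampleBackgroundPoints(el, 35, sc$presence, seed = rep)
    tr <- buildTrainingSet(sc$presence, bg, sc$stack)
    m <- fitBRT(tr, fastConfig(seed = rep), 60)
    ri <- relativeInfluence(m)
    if (ri["elev"] > ri["srad"] && ri["bio4"] > ri["srad"]) wins <- wins + 1L
  }
  expect_gte(wins, 4)
})
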