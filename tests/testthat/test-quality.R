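test_that("partialFTest matches hand arithmetic and is monotone", {
  r <- partialFTest(10, 10, 1, 13, 2)
  expect_equal(r$F, 0)
  expect_equal(r$p, 1)
  r2 <- partialFTest(10, 5, 1, 13, 2)
  expect_equal(r2$F, 10.0)
  ps <- vapply(seq(0.5, 5, 0.5), function(f)
    pf(f, 1, 10, lower.tail = FALSE), 0)
  expect_true(all(diff(ps) < 0))
  expect_error(partialFTest(5, 10, 1, 13, 2), "rssReduced")
  expect_error(partialFTest(10, 5, 1, 3, 2), "degrees of freedom")
})

test_that("stepwise recovers an exact linear truth", {
  withr::with_seed(41, {
    X <- data.frame(x1 = rnorm(30), x2 = rnorm(30))
  })
  y <- 2 + 3 * X$x1
  eq <- stepwiseRegression(y, X)
  expect_equal(names(eq@coefficients), "x1")
  expect_equal(eq@intercept, 2, tolerance = 1e-8)
  expect_equal(unname(eq@coefficients["x1"]), 3, tolerance = 1e-8)
  expect_equal(eq@rSquared, 1, tolerance = 1e-12)
  expect_error(stepwiseRegression(rep(1, 30), X), "constant")
})

test_that("pure-noise candidates rarely enter the model", {
  interceptOnly <- vapply(1:50, function(rep) {
    withr::with_seed(500 + rep, {
      X <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
      y <- rnorm(40)
    })
    eq <- stepwiseRegression(y, X)
    length(eq@coefficients) == 0
  }, TRUE)
  expect_gte(mean(interceptOnly), 0.85)
})

test_that("full-entry stepwise equals the OLS oracle", {
  withr::with_seed(43, {
    X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
    y <- 1 + 0.5 * X$a - 0.2 * X$b + rnorm(50)
  })
  eq <- stepwiseRegression(y, X, pEnter = 1, pRemove = 1)
  ref <- lm(y ~ a + b + c, data = X)
  expect_equal(sort(names(eq@coefficients)), c("a", "b", "c"))
  expect_equal(eq@intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  for (nm in c("a", "b", "c"))
    expect_equal(unname(eq@coefficients[nm]), unname(coef(ref)[nm]),
                 tolerance = 1e-8)
  expect_equal(eq@rSquared, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("collinear candidates are skipped with a log entry", {
  withr::with_seed(44, {
    X <- data.frame(a = rnorm(40))
    X$b <- 2 * X$a          # perfectly collinear with a
    y <- 5 + 4 * X$a + rnorm(40, 0, 0.3)
  })
  msgs <- capture_messages(eq <- stepwiseRegression(y, X))
  expect_true(length(eq@coefficients) == 1)
  expect_match(paste(msgs, collapse = " "), "collinear")
})

test_that("the y4-structure truth is recovered from simulated contents", {
  sc <- demoScene(seed = 47, ncols = 24, nrows = 24, nOccurrences = 80,
                  nPresence = 40)
  eqTruth <- builtinEquations()[[4]]  # bio3 and bio4 terms
  hits <- 0L; signsOk <- TRUE
  for (rep in 1:50) {
    pts <- withSeed(splitSeed(900, rep), {
      ok <- which(validMask(sc$stack))
      pick <- sample(ok, 50)
      rc <- arrayInd(pick, dim(validMask(sc$stack)))
      ctr <- pointFromCell(gridHeader(sc$stack), rc[, 1], rc[, 2])
      data.frame(lon = ctr[, "x"], lat = ctr[, "y"])
    })
    noise <- calibrateNoiseSd(pts, sc$stack, list(eqTruth), targetR2 = 0.4)
    tab <- suppressMessages(
      simulateCompoundContents(pts, sc$stack, list(eqTruth), noise,
                               seed = splitSeed(901, rep)))
    cand <- tab[, c("bio1", "bio3", "bio4")]
    eq <- stepwiseRegression(tab[[eqTruth@response]], cand)
    if (all(c("bio3", "bio4") %in% names(eq@coefficients))) {
      hits <- hits + 1L
      if (!(eq@coefficients["bio3"] < 0 && eq@coefficients["bio4"] > 0))
        signsOk <- FALSE
    }
  }
  expect_gte(hits, 40)  # >= 80% of 50 replicates
  expect_true(signsOk)
})

test_that("applyEquation computes the published equations cell-wise", {
  h <- GridHeader(2, 1)
  st <- buildStack(
    list(bio1 = rasterGrid(h, matrix(c(0, 10), 1)),
         bio3 = rasterGrid(h, matrix(c(0, 1000), 1)),
         bio4 = rasterGrid(h, matrix(c(0, 300), 1))),
    c(bio1 = "continuous", bio3 = "continuous", bio4 = "continuous"))
  eqs <- builtinEquations()
  # intercepts at the all-zero cell
  expect_equal(applyEquation(eqs[[1]], st)@values[1, 1], 0.021)
  # printed-coefficient arithmetic
  expect_equal(applyEquation(eqs[[3]], st)@values[1, 2],
               -0.05 + 0.000352 * 300, tolerance = 1e-12)
  expect_equal(applyEquation(eqs[[4]], st)@values[1, 2],
               14.493 - 0.01 * 1000 + 0.02 * 300, tolerance = 1e-12)
  expect_error(applyEquation(regressionEquation("x", 0, c(zz = 1)), st),
               "missing")
})

test_that("applyEquation is linear in the coefficients and propagates nodata", {
  st <- tinyStack(maskCells = cbind(2, 2))
  eq <- regressionEquation("t", 1.5, c(bio4 = 0.01, elev = -0.002))
  g1 <- applyEquation(eq, st)
  eq2 <- regressionEquation("t", 1.5, c(bio4 = 0.03, elev = -0.006))
  g2 <- applyEquation(eq2, st)
  vm <- validMask(st)
  expect_equal(g2@values[vm] - 1.5, 3 * (g1@values[vm] - 1.5),
               tolerance = 1e-10)
  expect_true(g1@mask[2, 2])
})

test_that("builtin equations carry the printed coefficients and R2", {
  eqs <- builtinEquations()
  expect_length(eqs, 5)
  y2 <- eqs[[2]]
  expect_equal(y2@intercept, -0.581)
  expect_equal(unname(y2@coefficients[c("bio1", "bio4")]), c(0.53, 0.021))
  expect_equal(eqs[[5]]@rSquared, 0.336)
  expect_equal(vapply(eqs, function(e) e@rSquared, 0),
               c(0.365, 0.327, 0.349, 0.304, 0.336))
})
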