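test_that("generateEnvStack is deterministic and honors degenerate specs", {
  h <- GridHeader(12, 12, cellsize = 1000)
  spec <- demoLayerSpec()
  a <- generateEnvStack(h, spec, seed = 5)
  b <- generateEnvStack(h, spec, seed = 5)
  expect_equal(getLayer(a, "elev")@values, getLayer(b, "elev")@values)
  expect_equal(getLayer(a, "soil")@values, getLayer(b, "soil")@values)

  flat <- generateEnvStack(h, list(list(name = "z", kind = "continuous",
                                        mean = 3, sd = 0,
                                        gradientAmplitude = 0)), seed = 1)
  expect_true(all(getLayer(flat, "z")@values == 3))

  expect_error(generateEnvStack(h, list(), seed = 1), "at least one layer")
})

test_that("categorical layers have at most k integer codes", {
  h <- GridHeader(15, 15)
  st <- generateEnvStack(h, list(list(name = "soil", kind = "categorical",
                                      k = 7)), seed = 2)
  codes <- unique(as.vector(getLayer(st, "soil")@values))
  expect_lte(length(codes), 7)
  expect_true(all(codes == round(codes)))
})

test_that("true suitability matches its closed form and bounds", {
  st <- tinyStack()
  tp <- truthParams("elev", "bio4", "soil", elevationThreshold = 1500,
                    precipBand = c(250, 400), logisticScale = 4,
                    elevWidth = 200, precipWidth = 75,
                    categoricalEffects = c("2" = 0.3))
  s <- computeTrueSuitability(st, tp)
  expect_true(all(s@values >= 0 & s@values <= 1))

  # hand-computed single cell
  r <- 3; c <- 4
  elev <- getLayer(st, "elev")@values[r, c]
  prec <- getLayer(st, "bio4")@values[r, c]
  soil <- getLayer(st, "soil")@values[r, c]
  sElev <- plogis((elev - 1500) / 200) - 0.5
  d <- max(250 - prec, prec - 400, 0)
  sPrec <- exp(-d^2 / (2 * 75^2)) - 0.5
  eff <- if (soil == 2) 0.3 else 0
  expect_equal(s@values[r, c], plogis(4 * (sElev + sPrec + eff)),
               tolerance = 1e-12)

  # all effects zero -> uniform 0.5
  tp0 <- truthParams("elev", "bio4", "soil", elevAmplitude = 0,
                     precipAmplitude = 0)
  expect_true(all(abs(computeTrueSuitability(st, tp0)@values - 0.5) < 1e-12))

  # high elevation, mid-band precipitation, no categorical effect -> > 0.5
  h1 <- GridHeader(1, 1)
  st1 <- buildStack(
    list(elev = rasterGrid(h1, matrix(2500)),
         bio4 = rasterGrid(h1, matrix(325)),
         soil = rasterGrid(h1, matrix(1))),
    c(elev = "continuous", bio4 = "continuous", soil = "categorical"))
  tp1 <- truthParams("elev", "bio4", "soil")
  expect_gt(computeTrueSuitability(st1, tp1)@values[1, 1], 0.5)

  expect_error(computeTrueSuitability(st, truthParams("nope", "bio4", "soil")),
               "missing")
})

test_that("occurrence sampling concentrates on suitable cells", {
  h <- GridHeader(4, 4)
  vals <- matrix(0, 4, 4); vals[2, 3] <- 1
  suit <- rasterGrid(h, vals)
  occ <- sampleOccurrences(suit, 5, seed = 3)
  cells <- cellFromPoint(h, occ$lon, occ$lat)
  expect_true(all(cells[, "row"] == 2 & cells[, "col"] == 3))

  expect_equal(sampleOccurrences(suit, 5, seed = 3),
               sampleOccurrences(suit, 5, seed = 3))
  expect_error(sampleOccurrences(rasterGrid(h, matrix(0, 4, 4)), 1, 1),
               "zero everywhere")
})

test_that("uniform suitability yields near-uniform per-cell counts", {
  h <- GridHeader(5, 5)
  suit <- rasterGrid(h, matrix(1, 5, 5))
  occ <- sampleOccurrences(suit, 10000, seed = 11)
  cells <- cellFromPoint(h, occ$lon, occ$lat)
  counts <- table(factor(paste(cells[, 1], cells[, 2]),
                         levels = as.vector(outer(1:5, 1:5, paste))))
  expectN <- 10000 / 25
  sdN <- sqrt(10000 * (1 / 25) * (24 / 25))
  expect_true(all(abs(counts - expectN) < 4 * sdN))
})

test_that("occurrence density converges to normalized suitability", {
  h <- GridHeader(10, 10)
  withr::with_seed(13, {
    vals <- matrix(runif(100, 0.2, 1), 10, 10)
  })
  suit <- rasterGrid(h, vals)
  occ <- sampleOccurrences(suit, 50000, seed = 17)
  cells <- cellFromPoint(h, occ$lon, occ$lat)
  counts <- as.vector(table(factor(paste(cells[, 1], cells[, 2]),
                                   levels = as.vector(outer(1:10, 1:10, paste)))))
  p <- as.vector(vals)  # column-major, matching the outer() level order
  p <- p / sum(p)
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("compound simulation matches the equations exactly at zero noise", {
  sc <- demoScene(seed = 3, ncols = 16, nrows = 16, nOccurrences = 50,
                  nPresence = 30)
  eqs <- builtinEquations()
  pts <- sampleOccurrences(sc$suitability, 20, seed = 21)
  zero <- setNames(rep(0, length(eqs)),
                   vapply(eqs, function(e) e@response, ""))
  tab <- simulateCompoundContents(pts, sc$stack, eqs, zero, seed = 5)
  for (eq in eqs) {
    expected <- eq@intercept
    for (nm in names(eq@coefficients))
      expected <- expected + eq@coefficients[[nm]] * tab[[nm]]
    expect_equal(tab[[eq@response]], pmax(expected, 0), tolerance = 1e-12)
  }
  # determinism
  noise <- calibrateNoiseSd(pts, sc$stack, eqs)
  t1 <- simulateCompoundContents(pts, sc$stack, eqs, noise, seed = 9)
  t2 <- simulateCompoundContents(pts, sc$stack, eqs, noise, seed = 9)
  expect_equal(t1, t2)
})

test_that("off-grid sample points are skipped with a count", {
  sc <- demoScene(seed = 4, ncols = 8, nrows = 8, nOccurrences = 30,
                  nPresence = 10)
  eqs <- builtinEquations()[3]
  pts <- rbind(sampleOccurrences(sc$suitability, 5, seed = 2),
               data.frame(id = 99, lon = -5000, lat = -5000))
  suppressMessages(
    tab <- simulateCompoundContents(pts, sc$stack, eqs,
                                    c(sweroside = 0), seed = 1))
  expect_equal(nrow(tab), 5)
  expect_equal(attr(tab, "nSkipped"), 1)
})

test_that("calibrated noise recovers the target R2 range over replicates", {
  sc <- demoScene(seed = 6, ncols = 24, nrows = 24, nOccurrences = 80,
                  nPresence = 40)
  eq <- builtinEquations()[[2]]  # gentiopicroside ~ bio1 + bio4
  r2 <- vapply(1:20, function(rep) {
    pts <- sampleOccurrences(sc$suitability, 50, seed = 100 + rep)
    noise <- calibrateNoiseSd(pts, sc$stack, list(eq), targetR2 = 0.35)
    tab <- simulateCompoundContents(pts, sc$stack, list(eq), noise,
                                    seed = 200 + rep)
    fit <- lm(tab[[eq@response]] ~ bio1 + bio4, data = tab)
    summary(fit)$r.squared
  }, 0)
  expect_true(all(r2 > 0.15 & r2 < 0.55))
})
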