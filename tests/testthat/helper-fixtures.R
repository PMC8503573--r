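# Shared fixtures, all built in code at test time.

# tiny aligned stack: continuous precip/elev plus a categorical layer
tinyStack <- function(nr = 6, nc = 6, maskCells = NULL) {
  h <- GridHeader(nc, nr, 0, 0, 1000)
  precip <- matrix(seq(150, 500, length.out = nr * nc), nr, nc)
  elev <- matrix(seq(600, 2000, length.out = nr * nc), nr, nc, byrow = TRUE)
  soil <- matrix(rep(1:3, length.out = nr * nc), nr, nc)
  if (!is.null(maskCells)) {
    precip[maskCells] <- NA
  }
  buildStack(
    list(bio4 = rasterGrid(h, precip), elev = rasterGrid(h, elev),
         soil = rasterGrid(h, soil)),
    c(bio4 = "continuous", elev = "continuous", soil = "categorical"))
}

# labelled feature data with a clean logistic signal on x1 (and weaker x2)
signalData <- function(n, seed, beta = c(3, 0.75)) {
  withr::with_seed(seed, {
    x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
    p <- plogis(beta[1] * x1 + beta[2] * x2)
    d <- data.frame(x1 = x1, x2 = x2, x3 = x3,
                    label = rbinom(n, 1, p))
    attr(d, "kinds") <- c(x1 = "continuous", x2 = "continuous",
                          x3 = "continuous")
    d
  })
}

fastConfig <- function(seed = 1, nFolds = 5, maxTrees = 150, ...) {
  fitConfig(learningRate = 0.1, stepSize = 10, maxTrees = maxTrees,
            minObs = 5, nFolds = nFolds, seed = seed, ...)
}

# brute-force AUC over all (positive, negative) pairs
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# exhaustive Jenks: enumerate all contiguous partitions of the sorted values
bruteJenksSSD <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) sum((x - mean(x))^2)
  cuts <- utils::combn(n - 1, k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], n)
    tot <- 0
    for (c2 in seq_len(k))
      tot <- tot + ssd(v[(bounds[c2] + 1):bounds[c2 + 1]])
    if (tot < best) best <- tot
  }
  best
}

# demo pipeline run, computed once and shared by the tests that need it
demoRunCache <- new.env(parent = emptyenv())
demoRunReport <- function() {
  if (is.null(demoRunCache$report)) {
    cfg <- defaultPipelineConfig(
      output_dir = file.path(tempdir(), "hq-demo-run"), seed = 42)
    demoRunCache$report <- suppressMessages(runPipeline(cfg))
  }
  demoRunCache$report
}
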