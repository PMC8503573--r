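#' @useDynLib HabitatQuality, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats plogis quantile rnorm runif sd lm pf anova var
#' @importFrom stats residuals coef setNames
#' @importFrom utils read.table write.table head
NULL

#' Derive a stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Sub-seeds
#' for independent stages (layer simulation, occurrence sampling, per-iteration
#' background draws, fold assignment, bagging) are derived deterministically
#' so that no two stages share an RNG stream and the whole pipeline is
#' reproducible from one integer.
#'
#' @param seed master seed (integer).
#' @param stream stream index (non-negative integer); each consumer uses a
#'   distinct index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' splitSeed(42, 1)
splitSeed <- function(seed, stream) {
  seed <- as.double(seed)
  stream <- as.double(stream)
  # affine scramble mod a Mersenne prime; keeps results in 32-bit range
  m <- 2147483647
  s <- (seed %% m) * 48271 %% m
  ((s + stream * 1000003 + 12345) %% m)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Leveled logger. Messages go through message() so tests and callers can
# suppress or capture them; when `file` is set they are appended there too.
logMsg <- function(..., level = "INFO", file = NULL) {
  txt <- sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                 paste0(..., collapse = ""))
  if (!is.null(file)) cat(txt, "\n", file = file, append = TRUE, sep = "")
  message(txt)
  invisible(txt)
}

# Bernoulli deviance (-2 * mean log-likelihood), guarded against p in {0,1}.
bernoulliDeviance <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}
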