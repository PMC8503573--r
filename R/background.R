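#' Screen background-eligible cells
#'
#' A cell is eligible as a background (pseudo-absence) point iff it is
#' jointly valid in the stack AND violates the suitable band: precipitation
#' strictly below `precipLow` or strictly above `precipHigh`, or elevation
#' strictly below `elevMin`. Boundary values (exactly 250, 400 or 800 under
#' the defaults) are NOT eligible.
#'
#' @param stack an [EnvStack-class].
#' @param rule a [ScreeningRule-class].
#' @return logical matrix, `TRUE` = background-eligible.
#' @export
screenBackgroundMask <- function(stack, rule) {
  for (nm in c(rule@precipLayer, rule@elevLayer))
    if (!nm %in% layerNames(stack))
      stop("screening layer '", nm, "' missing from stack")
  prec <- getLayer(stack, rule@precipLayer)@values
  elev <- getLayer(stack, rule@elevLayer)@values
  validMask(stack) &
    (prec < rule@precipLow | prec > rule@precipHigh | elev < rule@elevMin)
}

#' Sample background cells for one ensemble iteration
#'
#' Draws `n` distinct cells uniformly without replacement from the eligible
#' set minus the presence cells. Each ensemble iteration calls this with a
#' fresh derived seed, giving independent redraws.
#'
#' @param eligible logical matrix from [screenBackgroundMask].
#' @param n number of cells to draw.
#' @param exclude a [PresenceGrid-class] whose cells are never drawn.
#' @param seed RNG seed.
#' @return integer matrix with columns `row`, `col`.
#' @export
sampleBackgroundPoints <- function(eligible, n, exclude, seed) {
  el <- eligible
  if (!is.null(exclude) && nPresence(exclude) > 0)
    el[presenceCells(exclude)] <- FALSE
  avail <- which(el)
  if (length(avail) < n)
    stop(sprintf(
      "insufficient background cells: %d eligible (excluding presence), %d requested",
      length(avail), n))
  pick <- withSeed(seed, {
    if (length(avail) == n) avail else sample(avail, n)
  })
  rc <- arrayInd(pick, dim(eligible))
  colnames(rc) <- c("row", "col")
  rc
}

#' Build a presence/background training set
#'
#' Stacks presence rows (label 1) on top of background rows (label 0); with
#' equal-size presence and background sets of 246 cells this reproduces the
#' published 492-sample iteration design.
#'
#' @param presence a [PresenceGrid-class].
#' @param background integer cell matrix from [sampleBackgroundPoints].
#' @param stack an [EnvStack-class].
#' @return a feature table (see [extractFeatures]) with
#'   `nPresence + nrow(background)` rows.
#' @export
buildTrainingSet <- function(presence, background, stack) {
  pk <- paste(presenceCells(presence)[, 1], presenceCells(presence)[, 2])
  bk <- paste(background[, 1], background[, 2])
  if (length(intersect(pk, bk)))
    stop("presence and background cell sets overlap (",
         length(intersect(pk, bk)), " cells)")
  pres <- extractFeatures(presenceCells(presence), stack, 1)
  back <- extractFeatures(background, stack, 0)
  out <- rbind(pres, back)
  attr(out, "kinds") <- attr(pres, "kinds")
  rownames(out) <- NULL
  out
}
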