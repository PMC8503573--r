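#' Snap occurrence records to unique presence grid cells
#'
#' Each record is mapped to its grid cell by the half-open point-to-cell
#' convention (see [cellFromPoint]); within-cell duplicates are collapsed and
#' counted. Records outside the grid or on nodata cells are dropped with a
#' logged count rather than raising an error, since real gazetteer data is
#' messy. Cells are returned in order of first appearance in the record list.
#'
#' @param records data.frame with columns `lon`, `lat` (optional `id`).
#' @param stack reference [EnvStack-class].
#' @return a [PresenceGrid-class].
#' @export
gridOccurrences <- function(records, stack) {
  if (is.null(records) || nrow(records) == 0)
    stop("no occurrence records supplied")
  h <- gridHeader(stack)
  cells <- cellFromPoint(h, records$lon, records$lat)
  off <- is.na(cells[, 1])
  if (any(off))
    logMsg(sum(off), " occurrence record(s) outside the grid; dropped",
           level = "WARN")
  cells <- cells[!off, , drop = FALSE]
  vm <- validMask(stack)
  onData <- vm[cells]
  if (any(!onData))
    logMsg(sum(!onData), " occurrence record(s) on nodata cells; dropped",
           level = "WARN")
  cells <- cells[onData, , drop = FALSE]
  if (nrow(cells) == 0) stop("all occurrence records were dropped")
  key <- paste(cells[, 1], cells[, 2])
  first <- !duplicated(key)
  counts <- as.integer(table(factor(key, levels = key[first])))
  new("PresenceGrid", cells = cells[first, , drop = FALSE],
      counts = counts, header = h)
}

# Keep the first n presence cells (in first-appearance order). Used to pin
# a study design to a fixed presence-cell count.
trimPresence <- function(presence, n) {
  if (nPresence(presence) <= n) return(presence)
  keep <- seq_len(n)
  new("PresenceGrid", cells = presence@cells[keep, , drop = FALSE],
      counts = presence@counts[keep], header = presence@header)
}

#' Extract predictor feature rows for cells
#'
#' Builds one labelled row per cell holding every stack layer's value. Rows
#' touching nodata in any layer are dropped with a logged count; it is an
#' error if nothing remains.
#'
#' @param cells integer matrix with columns `row`, `col` (e.g.
#'   [presenceCells]).
#' @param stack an [EnvStack-class].
#' @param label 0 (background) or 1 (presence), attached to every row.
#' @return a feature table: data.frame of predictor columns plus `label`,
#'   with a `kinds` attribute naming each predictor's kind.
#' @export
extractFeatures <- function(cells, stack, label) {
  stopifnot(label %in% c(0, 1))
  cells <- as.matrix(cells)
  vm <- validMask(stack)
  ok <- vm[cells]
  if (any(!ok))
    logMsg(sum(!ok), " cell(s) on nodata; feature rows dropped",
           level = "WARN")
  cells <- cells[ok, , drop = FALSE]
  if (nrow(cells) == 0) stop("no valid cells to extract features from")
  vals <- vapply(layerNames(stack), function(nm)
    getLayer(stack, nm)@values[cells], numeric(nrow(cells)))
  df <- as.data.frame(matrix(vals, nrow = nrow(cells),
                             dimnames = list(NULL, layerNames(stack))))
  df$label <- as.integer(label)
  attr(df, "kinds") <- layerKinds(stack)
  df
}
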