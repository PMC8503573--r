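#' Read an ESRI ASCII grid
#'
#' Parses the six-keyword header (case-insensitive; `NODATA_VALUE` optional,
#' defaulting to -9999) followed by `nrows` rows of `ncols` values, north row
#' first. The `XLLCENTER`/`YLLCENTER` dialect is converted to the corner
#' convention by shifting half a cell. Cells equal to the nodata value (exact
#' comparison after parsing) are masked.
#'
#' @param path path to a `.asc` file.
#' @return a [RasterGrid-class].
#' @export
#' @examples
#' f <- tempfile(fileext = ".asc")
#' writeAsc(rasterGrid(GridHeader(2, 2), matrix(1:4, 2)), f)
#' readAsc(f)
readAsc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  centerX <- FALSE
  centerY <- FALSE
  i <- 1
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                    "yllcenter", "cellsize", "nodata_value")) break
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("malformed header line in ", path, ": '", lines[i], "'")
    val <- as.numeric(parts[2])
    if (key == "xllcenter") { key <- "xllcorner"; centerX <- TRUE }
    if (key == "yllcenter") { key <- "yllcorner"; centerY <- TRUE }
    hdr[[key]] <- val
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("header of ", path, " lacks keyword(s): ",
         paste(toupper(missing), collapse = ", "))
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  if (centerX) hdr$xllcorner <- hdr$xllcorner - hdr$cellsize / 2
  if (centerY) hdr$yllcorner <- hdr$yllcorner - hdr$cellsize / 2
  h <- GridHeader(hdr$ncols, hdr$nrows, hdr$xllcorner, hdr$yllcorner,
                  hdr$cellsize, hdr$nodata_value)
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(lines[seq(i, length(lines))]), "\\s+"))))
  if (anyNA(vals)) stop("non-numeric data value in ", path)
  if (length(vals) != h@nrows * h@ncols)
    stop(sprintf("dimension mismatch in %s: header says %d x %d = %d values, found %d",
                 path, h@nrows, h@ncols, h@nrows * h@ncols, length(vals)))
  values <- matrix(vals, nrow = h@nrows, ncol = h@ncols, byrow = TRUE)
  mask <- values == h@nodata
  new("RasterGrid", header = h, values = values, mask = mask)
}

#' Write an ESRI ASCII grid
#'
#' Emits `NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE` then data
#' rows north to south. Masked cells are written as the nodata value. Numbers
#' are printed with up to 17 significant digits so doubles round-trip exactly.
#'
#' @param grid a [RasterGrid-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAsc <- function(grid, path) {
  stopifnot(is(grid, "RasterGrid"))
  validObject(grid)
  h <- grid@header
  num <- function(x) {
    s <- sprintf("%.17g", x)
    # strip trailing zeros only in a plain decimal fraction
    dec <- grepl("\\.", s) & !grepl("[eE]", s)
    s[dec] <- sub("\\.$", "", sub("0+$", "", s[dec]))
    s
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(c(
    paste("NCOLS", h@ncols), paste("NROWS", h@nrows),
    paste("XLLCORNER", num(h@xllcorner)), paste("YLLCORNER", num(h@yllcorner)),
    paste("CELLSIZE", num(h@cellsize)),
    paste("NODATA_VALUE", num(h@nodata))), con)
  v <- grid@values
  v[grid@mask] <- h@nodata
  for (r in seq_len(h@nrows))
    writeLines(paste(vapply(v[r, ], num, ""), collapse = " "), con)
  invisible(path)
}

headersEqual <- function(a, b) {
  fields <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  diffs <- fields[vapply(fields, function(f)
    !isTRUE(all.equal(slot(a, f), slot(b, f), tolerance = 1e-9)), TRUE)]
  diffs
}

#' Assemble aligned layers into an EnvStack
#'
#' Verifies that every layer shares the reference header (nodata values may
#' differ) and computes the joint valid-cell mask as the intersection of the
#' layers' unmasked cells. Categorical layers must hold integer codes on
#' valid cells.
#'
#' @param grids named list of [RasterGrid-class].
#' @param kinds named character vector (`"continuous"`/`"categorical"`), one
#'   entry per layer.
#' @return an [EnvStack-class].
#' @export
#' @examples
#' h <- GridHeader(3, 3)
#' g <- rasterGrid(h, matrix(rnorm(9), 3))
#' buildStack(list(a = g, b = g), c(a = "continuous", b = "continuous"))
buildStack <- function(grids, kinds) {
  if (length(grids) < 1) stop("at least one layer is required")
  if (is.null(names(grids))) stop("layers must be named")
  ref <- grids[[1]]@header
  for (nm in names(grids)) {
    d <- headersEqual(ref, grids[[nm]]@header)
    if (length(d))
      stop("layer '", nm, "' is not aligned with '", names(grids)[1],
           "': differing header field(s) ", paste(d, collapse = ", "))
  }
  vm <- !Reduce(`|`, lapply(grids, function(g) g@mask))
  for (nm in names(grids)) {
    if (identical(unname(kinds[[nm]]), "categorical")) {
      v <- grids[[nm]]@values[vm]
      if (any(v != round(v)))
        stop("categorical layer '", nm, "' has non-integer codes")
    }
  }
  new("EnvStack", layers = grids, kinds = kinds, validMask = vm)
}

#' Read or write a layer manifest
#'
#' A manifest is a delimited text file with header `name,path,kind` declaring
#' the layers of a stack. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @return [readStackManifest] returns an [EnvStack-class].
#' @export
readStackManifest <- function(path) {
  m <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  if (!all(c("name", "path", "kind") %in% names(m)))
    stop("manifest must have columns name, path, kind")
  base <- dirname(path)
  grids <- lapply(m$path, function(p) {
    if (!file.exists(p) && file.exists(file.path(base, p)))
      p <- file.path(base, p)
    readAsc(p)
  })
  names(grids) <- m$name
  buildStack(grids, stats::setNames(m$kind, m$name))
}

#' @rdname readStackManifest
#' @param stack an [EnvStack-class] to write.
#' @param dir directory receiving one `.asc` per layer plus `manifest.csv`.
#' @return [writeStackManifest] returns the manifest path, invisibly.
#' @export
writeStackManifest <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(layerNames(stack), ".asc")
  for (i in seq_along(files))
    writeAsc(stack@layers[[i]], file.path(dir, files[i]))
  m <- data.frame(name = layerNames(stack), path = files,
                  kind = unname(layerKinds(stack)))
  mp <- file.path(dir, "manifest.csv")
  write.table(m, mp, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(mp)
}

#' Map between points and grid cells
#'
#' Cells are half-open: a point maps to column
#' `floor((x - xllcorner)/cellsize)` and row
#' `nrows - 1 - floor((y - yllcorner)/cellsize)` (0-based internally; returned
#' 1-based). Points on the east or north outer boundary, or outside the grid,
#' map to `NA`. `pointFromCell` is its exact inverse for interior points and
#' returns cell centers.
#'
#' @param header a [GridHeader-class].
#' @param x,y point coordinates (vectorized).
#' @return `cellFromPoint`: integer matrix with columns `row`, `col` (1-based;
#'   `NA` rows for out-of-grid points). `pointFromCell`: numeric matrix with
#'   columns `x`, `y` of cell centers.
#' @export
cellFromPoint <- function(header, x, y) {
  cc <- floor((x - header@xllcorner) / header@cellsize)
  rr <- floor((y - header@yllcorner) / header@cellsize)
  bad <- cc < 0 | cc >= header@ncols | rr < 0 | rr >= header@nrows
  r1 <- header@nrows - 1L - as.integer(rr) + 1L
  c1 <- as.integer(cc) + 1L
  r1[bad] <- NA_integer_
  c1[bad] <- NA_integer_
  cbind(row = r1, col = c1)
}

#' @rdname cellFromPoint
#' @param row,col 1-based cell indices (vectorized).
#' @export
pointFromCell <- function(header, row, col) {
  x <- header@xllcorner + (col - 1 + 0.5) * header@cellsize
  y <- header@yllcorner + (header@nrows - row + 0.5) * header@cellsize
  cbind(x = x, y = y)
}
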