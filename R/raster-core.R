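# Grid I/O, alignment checks and min-max normalization.
#
# Rasters are read and written in the ESRI ASCII grid format (.asc): a
# six-line text header (ncols, nrows, xllcorner, yllcorner, cellsize,
# NODATA_value) followed by rows of cell values from the northern edge
# downward, with an optional <name>.prj sidecar holding the CRS tag.

.asciiHeaderKeys <- c("ncols", "nrows", "xllcorner", "yllcorner",
                      "cellsize", "nodata_value")

#' Read a single-band raster from an ESRI ASCII grid file
#'
#' Parses the header, the value rows (top row = northern edge) and, when a
#' sidecar \code{<name>.prj} file is present, the CRS tag. Cells equal to the
#' header's nodata sentinel are returned as \code{NA}.
#'
#' @param path path to a \code{.asc} file.
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- RasterGrid(matrix(runif(12), 3, 4), c(0, 1500, 500))
#' f <- tempfile(fileext = ".asc")
#' writeAsciiGrid(g, f)
#' g2 <- readAsciiGrid(f)
#' all.equal(gridValues(g), gridValues(g2))
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7L)
    stop("not an ASCII grid (file too short): ", path)
  hdr <- list()
  for (i in 1:6) {
    parts <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1L]]
    if (length(parts) != 2L)
      stop("malformed ASCII grid header at line ", i, ": ", path)
    key <- tolower(parts[[1L]])
    val <- suppressWarnings(as.numeric(parts[[2L]]))
    if (!(key %in% .asciiHeaderKeys) || is.na(val))
      stop("malformed ASCII grid header ('", parts[[1L]], "'): ", path)
    hdr[[key]] <- val
  }
  if (!all(.asciiHeaderKeys %in% names(hdr)))
    stop("ASCII grid header incomplete: ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- paste(lines[-(1:6)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "[[:space:]]+")[[1L]]))
  if (anyNA(vals))
    stop("non-numeric cell values in ASCII grid: ", path)
  if (length(vals) != nr * nc)
    stop("ASCII grid body does not match header dimensions: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  crs <- "unspecified"
  prj <- paste0(tools::file_path_sans_ext(path), ".prj")
  if (file.exists(prj)) {
    txt <- readLines(prj, warn = FALSE)
    if (length(txt)) crs <- trimws(txt[[1L]])
  }
  RasterGrid(m,
             transform = c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                           hdr$cellsize),
             crs = crs)
}

#' Write a RasterGrid to an ESRI ASCII grid file
#'
#' Inverse of \code{\link{readAsciiGrid}}: values, georeference and nodata
#' cells round-trip exactly (values are printed with 17 significant digits).
#' A \code{<name>.prj} sidecar receives the CRS tag.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param path output path; overwritten if it exists.
#' @param nodata sentinel written for \code{NA} cells (default -9999).
#' @return \code{path}, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  stopifnot(is(grid, "RasterGrid"))
  v <- gridValues(grid)
  ok <- v[!is.na(v)]
  if (length(ok) && any(ok == nodata))
    stop("a data cell equals the nodata sentinel ", nodata,
         "; choose a different sentinel")
  tr <- gridTransform(grid)
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", tr[[1L]]),
    sprintf("yllcorner %.10g", tr[[2L]] - nrow(v) * tr[[3L]]),
    sprintf("cellsize %.10g", tr[[3L]]),
    sprintf("NODATA_value %.10g", nodata))
  out <- v
  out[is.na(out)] <- nodata
  rows <- apply(out, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  writeLines(crsTag(grid), paste0(tools::file_path_sans_ext(path), ".prj"))
  invisible(path)
}

#' Check that a set of grids share one geometry
#'
#' Downstream stages require exact co-registration; this reports every
#' mismatch in shape, origin, cell size or CRS tag against the first grid.
#'
#' @param grids list of \linkS4class{RasterGrid}s (length >= 1).
#' @return list with \code{pass} (logical) and \code{mismatches}
#'   (character vector naming each failing property).
#' @export
alignCheck <- function(grids) {
  stopifnot(length(grids) >= 1L)
  ref <- grids[[1L]]
  mism <- character()
  for (i in seq_along(grids)[-1L]) {
    g <- grids[[i]]
    if (!identical(dim(gridValues(g)), dim(gridValues(ref))))
      mism <- c(mism, sprintf("grid %d: shape mismatch", i))
    tr <- gridTransform(g); tref <- gridTransform(ref)
    if (tr[[3L]] != tref[[3L]])
      mism <- c(mism, sprintf("grid %d: cell_size mismatch", i))
    if (tr[[1L]] != tref[[1L]] || tr[[2L]] != tref[[2L]])
      mism <- c(mism, sprintf("grid %d: origin mismatch", i))
    if (!identical(crsTag(g), crsTag(ref)))
      mism <- c(mism, sprintf("grid %d: crs mismatch", i))
  }
  list(pass = length(mism) == 0L, mismatches = mism)
}

#' Stop unless grids are aligned
#' @param grids list of RasterGrids.
#' @param what context for the error message.
#' @return invisibly TRUE.
#' @export
assertAligned <- function(grids, what = "input grids") {
  rep <- alignCheck(grids)
  if (!rep$pass)
    stop(what, " are not aligned: ", paste(rep$mismatches, collapse = "; "))
  invisible(TRUE)
}

#' Min-max normalize a grid to [0, 1]
#'
#' Rescales unmasked cells as \code{(x - min) / (max - min)} so the layer
#' attains 0 and 1; masked cells (NA, plus any cell flagged in \code{mask})
#' stay masked. This is the per-image normalization applied to every
#' component indicator before PCA.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param mask optional logical matrix, TRUE = exclude (e.g. water).
#' @param layerName name used in the degenerate-range error message.
#' @return A \linkS4class{RasterGrid} with unmasked values in [0, 1].
#' @export
minmaxNormalize <- function(grid, mask = NULL, layerName = "layer") {
  v <- gridValues(grid)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), identical(dim(mask), dim(v)))
    v[mask] <- NA_real_
  }
  ok <- !is.na(v)
  if (sum(ok) < 2L)
    stop("minmaxNormalize: fewer than 2 unmasked cells in ", layerName)
  lo <- min(v[ok]); hi <- max(v[ok])
  if (hi == lo)
    stop("degenerate range (max == min) in ", layerName)
  out <- (v - lo) / (hi - lo)
  setGridValues(grid, out)
}
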