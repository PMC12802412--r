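#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib rseikit, .registration = TRUE
NULL

#' RasterGrid: a single-band north-up raster on a projected grid
#'
#' The elementary data container of the package: a numeric matrix of cell
#' values (row 1 = northernmost row, column 1 = westernmost column) plus an
#' affine georeference restricted to north-up square cells. Nodata cells are
#' stored as \code{NA}; every statistic computed downstream excludes them.
#'
#' @slot values numeric matrix; \code{NA} marks nodata cells.
#' @slot transform named numeric of length 3: \code{origin_x}, \code{origin_y}
#'   (map coordinates of the outer corner of the top-left cell) and
#'   \code{cell_size} (> 0, map units, square cells).
#' @slot crs character scalar tagging the projected CRS (free text, e.g.
#'   an EPSG string); compared verbatim by \code{\link{alignCheck}}.
#' @export
setClass("RasterGrid",
  representation(values = "matrix", transform = "numeric", crs = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (length(object@transform) != 3L || any(!is.finite(object@transform)))
      msg <- c(msg, "transform must be 3 finite numbers (origin_x, origin_y, cell_size)")
    else if (object@transform[[3L]] <= 0)
      msg <- c(msg, "cell_size must be > 0")
    if (length(object@crs) != 1L)
      msg <- c(msg, "crs must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a RasterGrid
#'
#' @param values numeric matrix (NA = nodata).
#' @param transform numeric length-3 vector \code{(origin_x, origin_y,
#'   cell_size)}; origin is the top-left corner, cell_size in map units.
#' @param crs CRS tag (free text).
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- RasterGrid(matrix(1:12, 3, 4), c(0, 1500, 500), "EPSG:32648")
#' dim(gridValues(g))
#' @export
RasterGrid <- function(values, transform = c(0, nrow(values) * 500, 500),
                       crs = "local") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  transform <- as.numeric(transform)
  names(transform) <- c("origin_x", "origin_y", "cell_size")
  new("RasterGrid", values = values, transform = transform, crs = crs)
}

#' @describeIn RasterGrid cell-value matrix accessor
#' @param x a RasterGrid
#' @export
gridValues <- function(x) x@values

#' @describeIn RasterGrid georeference accessor
#' @export
gridTransform <- function(x) x@transform

#' @describeIn RasterGrid cell size (map units) accessor
#' @export
cellSize <- function(x) unname(x@transform[[3L]])

#' @describeIn RasterGrid CRS tag accessor
#' @export
crsTag <- function(x) x@crs

#' @describeIn RasterGrid logical matrix of nodata cells
#' @export
nodataMask <- function(x) is.na(x@values)

#' Replace the values of a RasterGrid, keeping its georeference
#'
#' @param x a RasterGrid supplying geometry.
#' @param values replacement matrix of identical shape.
#' @return A RasterGrid with the new values.
#' @export
setGridValues <- function(x, values) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!identical(dim(values), dim(x@values)))
    stop("replacement values must match the grid shape")
  initialize(x, values = values)
}

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("RasterGrid %d x %d, cell %g, origin (%g, %g), crs '%s'\n",
              nrow(v), ncol(v), object@transform[[3L]],
              object@transform[[1L]], object@transform[[2L]], object@crs))
  ok <- v[!is.na(v)]
  if (length(ok))
    cat(sprintf("  values: min %.4g, mean %.4g, max %.4g; nodata %d/%d\n",
                min(ok), mean(ok), max(ok), sum(is.na(v)), length(v)))
  else cat("  all cells nodata\n")
})

#' BandStack: co-registered reflectance bands plus an LST DN grid
#'
#' One observation epoch: surface-reflectance bands b1 (red), b2 (NIR),
#' b4 (green), b6 (SWIR1), b7 (SWIR2) scaled to reflectance units, and a
#' land-surface-temperature grid in sensor digital numbers. All member grids
#' must share shape, transform and CRS; the union of their nodata masks is
#' the stack's invalid set.
#'
#' @slot bands named list of \linkS4class{RasterGrid}s, names
#'   \code{b1, b2, b4, b6, b7}.
#' @slot lstDn \linkS4class{RasterGrid} of LST digital numbers.
#' @slot epoch character label, e.g. \code{"2001"}.
#' @export
setClass("BandStack",
  representation(bands = "list", lstDn = "RasterGrid", epoch = "character"),
  validity = function(object) {
    need <- c("b1", "b2", "b4", "b6", "b7")
    if (!all(need %in% names(object@bands)))
      return(paste("bands must contain", paste(need, collapse = ", ")))
    grids <- c(object@bands[need], list(object@lstDn))
    rep <- alignCheck(grids)
    if (!rep$pass)
      return(paste("member grids misaligned:", paste(rep$mismatches, collapse = "; ")))
    TRUE
  }
)

#' Construct a BandStack
#'
#' @param bands named list of RasterGrids with names b1, b2, b4, b6, b7.
#' @param lstDn RasterGrid of LST digital numbers on the same grid.
#' @param epoch epoch label.
#' @return A \linkS4class{BandStack}.
#' @export
BandStack <- function(bands, lstDn, epoch = "epoch") {
  new("BandStack", bands = bands, lstDn = lstDn, epoch = epoch)
}

#' @describeIn BandStack extract one member band grid
#' @param x a BandStack
#' @param name one of "b1","b2","b4","b6","b7","lst_dn"
#' @export
stackBand <- function(x, name) {
  if (name == "lst_dn") return(x@lstDn)
  b <- x@bands[[name]]
  if (is.null(b)) stop("no band named '", name, "'")
  b
}

#' @describeIn BandStack epoch label accessor
#' @export
epochLabel <- function(x) x@epoch

#' @describeIn BandStack logical matrix: union of member nodata masks
#' @export
stackInvalidMask <- function(x) {
  m <- nodataMask(x@lstDn)
  for (b in x@bands) m <- m | nodataMask(b)
  m
}

setMethod("show", "BandStack", function(object) {
  d <- dim(gridValues(object@lstDn))
  cat(sprintf("BandStack epoch '%s': %d x %d cells, bands %s + lst_dn\n",
              object@epoch, d[1L], d[2L],
              paste(names(object@bands), collapse = ",")))
})

#' IndicatorSet: the five water-masked ecological component layers
#'
#' Houses SAVI (greenness), SWCI (humidity), NDBBI (dryness), LST (heat,
#' Celsius) and CSI (salinity) on a common grid, together with the water mask
#' used to exclude open water from the assessment. When \code{normalized} is
#' TRUE each layer has been min-max rescaled to [0, 1] over land cells.
#'
#' @slot layers named list of \linkS4class{RasterGrid}s:
#'   \code{savi, swci, ndbbi, lst, csi} (that order is the loading order used
#'   by the PCA stage).
#' @slot waterMask logical matrix, TRUE = water.
#' @slot normalized logical flag.
#' @export
setClass("IndicatorSet",
  representation(layers = "list", waterMask = "matrix", normalized = "logical"),
  validity = function(object) {
    need <- c("savi", "swci", "ndbbi", "lst", "csi")
    if (!identical(names(object@layers), need))
      return(paste("layers must be exactly", paste(need, collapse = ", ")))
    rep <- alignCheck(object@layers)
    if (!rep$pass) return("indicator layers misaligned")
    if (!is.logical(object@waterMask) ||
        !identical(dim(object@waterMask), dim(gridValues(object@layers[[1L]]))))
      return("waterMask must be a logical matrix congruent with the layers")
    if (object@normalized) {
      for (nm in need) {
        v <- gridValues(object@layers[[nm]])
        v <- v[!is.na(v)]
        if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
          return(paste("normalized layer", nm, "outside [0,1]"))
      }
    }
    TRUE
  }
)

#' @describeIn IndicatorSet extract one indicator layer
#' @param x an IndicatorSet
#' @param name one of "savi","swci","ndbbi","lst","csi"
#' @export
indicatorLayer <- function(x, name) {
  l <- x@layers[[name]]
  if (is.null(l)) stop("no indicator named '", name, "'")
  l
}

#' @describeIn IndicatorSet names of the indicator layers, in loading order
#' @export
indicatorNames <- function(x) names(x@layers)

#' @describeIn IndicatorSet water mask accessor (TRUE = water)
#' @export
waterMask <- function(x) x@waterMask

#' @describeIn IndicatorSet TRUE once layers are min-max normalized
#' @export
isNormalized <- function(x) x@normalized

setMethod("show", "IndicatorSet", function(object) {
  d <- dim(object@waterMask)
  cat(sprintf("IndicatorSet %d x %d (%s), water %.1f%%, land %d cells\n",
              d[1L], d[2L],
              if (object@normalized) "normalized" else "raw",
              100 * mean(object@waterMask),
              sum(!is.na(gridValues(object@layers$savi)))))
})

#' PcaResult: eigen-structure of the indicator covariance
#'
#' @slot loadings p x p matrix, one unit-norm eigenvector per column,
#'   rows in indicator order.
#' @slot eigenvalues nonnegative, descending.
#' @slot contributions eigenvalue shares, sum 1.
#' @slot center column means removed before projection.
#' @slot oriented TRUE if PC1 scores were negated so the index increases
#'   with greenness.
#' @slot indicators row names of the loadings.
#' @export
setClass("PcaResult",
  representation(loadings = "matrix", eigenvalues = "numeric",
                 contributions = "numeric", center = "numeric",
                 oriented = "logical", indicators = "character"),
  validity = function(object) {
    msg <- character()
    if (abs(sum(object@contributions) - 1) > 1e-10)
      msg <- c(msg, "contribution rates must sum to 1")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
      msg <- c(msg, "eigenvalues must be sorted descending")
    if (any(object@eigenvalues < -1e-10))
      msg <- c(msg, "eigenvalues must be nonnegative")
    nrm <- sqrt(colSums(object@loadings^2))
    if (any(abs(nrm - 1) > 1e-8))
      msg <- c(msg, "loading vectors must have unit norm")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "PcaResult", function(object) {
  cat(sprintf("PcaResult on %d indicators; PC1 contribution %.2f%%%s\n",
              length(object@indicators), 100 * object@contributions[1L],
              if (object@oriented) " (PC1 negated for orientation)" else ""))
})

#' @describeIn PcaResult loadings matrix (indicators x components)
#' @param x a PcaResult
#' @export
pcaLoadings <- function(x) x@loadings

#' @describeIn PcaResult eigenvalues, descending
#' @export
pcaEigenvalues <- function(x) x@eigenvalues

#' @describeIn PcaResult eigenvalue shares (sum to 1)
#' @export
contributionRates <- function(x) x@contributions

#' @describeIn PcaResult TRUE if PC1 was negated during orientation
#' @export
isOriented <- function(x) x@oriented

#' RseiResult: the composite ecological index for one epoch
#'
#' @slot rsei \linkS4class{RasterGrid} in [0, 1] over land.
#' @slot classes integer-valued \linkS4class{RasterGrid}, grades I..V as 1..5.
#' @slot pca the \linkS4class{PcaResult} behind the index.
#' @slot classAreas data.frame: class, label, cells, area_km2, percent.
#' @slot indicatorCorrelations Pearson r between each indicator and the index.
#' @export
setClass("RseiResult",
  representation(rsei = "RasterGrid", classes = "RasterGrid",
                 pca = "PcaResult", classAreas = "data.frame",
                 indicatorCorrelations = "numeric"))

setMethod("show", "RseiResult", function(object) {
  v <- gridValues(object@rsei)
  cat(sprintf(
    "RseiResult: %d land cells, mean index %.3f, PC1 contribution %.2f%%\n",
    sum(!is.na(v)), mean(v, na.rm = TRUE),
    100 * object@pca@contributions[1L]))
})

#' @describeIn RseiResult index grid accessor
#' @param x an RseiResult
#' @export
rseiGrid <- function(x) x@rsei

#' @describeIn RseiResult class grid accessor (codes 1..5)
#' @export
rseiClasses <- function(x) x@classes

#' @describeIn RseiResult PCA accessor
#' @export
rseiPca <- function(x) x@pca

#' @describeIn RseiResult per-class area table
#' @export
classAreas <- function(x) x@classAreas

#' @describeIn RseiResult indicator-index Pearson correlations
#' @export
indicatorCorrelations <- function(x) x@indicatorCorrelations

#' ChangeSummary: grade change between two epochs
#'
#' @slot deltaGrade integer-valued \linkS4class{RasterGrid} in [-4, 4].
#' @slot changeType integer-coded \linkS4class{RasterGrid}, 1..5 =
#'   deteriorated significantly / deteriorated / unchanged / improved /
#'   improved significantly.
#' @slot transitions data.frame of FROM-TO pairs: from, to, cells, area_km2,
#'   percent.
#' @export
setClass("ChangeSummary",
  representation(deltaGrade = "RasterGrid", changeType = "RasterGrid",
                 transitions = "data.frame"))

setMethod("show", "ChangeSummary", function(object) {
  d <- gridValues(object@deltaGrade)
  cat(sprintf("ChangeSummary: %d joint cells, mean delta %.2f, %d transitions\n",
              sum(!is.na(d)), mean(d, na.rm = TRUE), nrow(object@transitions)))
})

#' @describeIn ChangeSummary delta-grade grid accessor
#' @param x a ChangeSummary
#' @export
deltaGrade <- function(x) x@deltaGrade

#' @describeIn ChangeSummary change-type grid accessor
#' @export
changeType <- function(x) x@changeType

#' @describeIn ChangeSummary FROM-TO transition table accessor
#' @export
transitions <- function(x) x@transitions

#' StabilityPersistence: temporal variability and persistence maps
#'
#' @slot cv coefficient-of-variation \linkS4class{RasterGrid} (>= 0).
#' @slot cvLevel integer-valued grid, stability levels 1..5.
#' @slot hurst Hurst-exponent grid in (0, 1].
#' @slot hurstClass integer-coded grid, 1..4 = strong antisustainability /
#'   weak antisustainability / weak sustainability / strong sustainability.
#' @export
setClass("StabilityPersistence",
  representation(cv = "RasterGrid", cvLevel = "RasterGrid",
                 hurst = "RasterGrid", hurstClass = "RasterGrid"))

setMethod("show", "StabilityPersistence", function(object) {
  cv <- gridValues(object@cv); h <- gridValues(object@hurst)
  cat(sprintf("StabilityPersistence: mean CV %.3f, mean H %.3f over %d cells\n",
              mean(cv, na.rm = TRUE), mean(h, na.rm = TRUE),
              sum(!is.na(cv))))
})

#' Discretization: one stratification of a continuous factor
#'
#' @slot method one of equal_interval, natural_breaks, quantile, geometric,
#'   std_dev.
#' @slot k realized number of classes (after degenerate-bin merging).
#' @slot breaks ascending interior cut points (length k - 1).
#' @slot labels integer stratum index per sample (NA where input missing).
#' @slot q explained-variance q-statistic, NA until evaluated.
#' @export
setClass("Discretization",
  representation(method = "character", k = "integer", breaks = "numeric",
                 labels = "integer", q = "numeric"),
  validity = function(object) {
    if (length(object@breaks) != object@k - 1L)
      return("breaks must have length k - 1")
    if (is.unsorted(object@breaks, strictly = TRUE) && length(object@breaks) > 1L)
      return("breaks must be strictly ascending")
    TRUE
  }
)

setMethod("show", "Discretization", function(object) {
  cat(sprintf("Discretization: %s, k = %d%s\n", object@method, object@k,
              if (is.na(object@q)) "" else sprintf(", q = %.4f", object@q)))
})

#' OpgdResult: optimal-parameter geographical detector output
#'
#' @slot factorTable data.frame: factor, method, k, q, p_value, sorted by q
#'   descending.
#' @slot interactionTable data.frame: factor_i, factor_j, q_i, q_j, q_ij,
#'   category.
#' @slot discretizations named list of the winning \linkS4class{Discretization}
#'   (or raw-category label vector) per factor.
#' @export
setClass("OpgdResult",
  representation(factorTable = "data.frame", interactionTable = "data.frame",
                 discretizations = "list"))

setMethod("show", "OpgdResult", function(object) {
  cat(sprintf("OpgdResult: %d factors, %d interactions; top factor %s (q = %.3f)\n",
              nrow(object@factorTable), nrow(object@interactionTable),
              object@factorTable$factor[1L], object@factorTable$q[1L]))
})

#' @describeIn OpgdResult per-factor q table accessor
#' @param x an OpgdResult
#' @export
factorTable <- function(x) x@factorTable

#' @describeIn OpgdResult pairwise interaction table accessor
#' @export
interactionTable <- function(x) x@interactionTable
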