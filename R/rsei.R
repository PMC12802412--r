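# PCA fusion of the normalized indicators into the composite index.
#
# The index is the first principal component of the 5-layer covariance over
# land cells, oriented so it increases with greenness (equivalent to the
# conditional "1 - PC1" convention), then min-max rescaled to [0, 1] and
# graded into five classes: bad [0,0.2), poor [0.2,0.4), moderate [0.4,0.6),
# good [0.6,0.8), excellent [0.8,1].

.rseiClassLabels <- c("bad", "poor", "moderate", "good", "excellent")
.changeTypeLabels <- c("deteriorated significantly", "deteriorated",
                       "unchanged", "improved", "improved significantly")

#' Land-cell value matrix of an IndicatorSet
#'
#' One row per land cell (water and nodata excluded listwise across the five
#' layers), columns in loading order savi, swci, ndbbi, lst, csi.
#'
#' @param indset an \linkS4class{IndicatorSet}.
#' @return list with \code{x} (matrix) and \code{idx} (linear cell indices).
#' @export
indicatorMatrix <- function(indset) {
  cols <- lapply(indset@layers, function(l) as.vector(gridValues(l)))
  x <- do.call(cbind, cols)
  colnames(x) <- names(indset@layers)
  keep <- stats::complete.cases(x)
  list(x = x[keep, , drop = FALSE], idx = which(keep))
}

#' Principal-component analysis of indicator layers
#'
#' Eigen-decomposition of the covariance matrix of the normalized indicator
#' values over land cells (covariance, not correlation: the layers are
#' already on a common [0, 1] scale). Components are sorted by eigenvalue;
#' contribution rates are eigenvalue shares of the trace.
#'
#' @param x an \linkS4class{IndicatorSet} or a numeric matrix with one row
#'   per observation and one column per indicator (any number >= 2 of
#'   indicators is accepted).
#' @param useCorrelation fit on the correlation matrix instead (non-default
#'   variant).
#' @return A \linkS4class{PcaResult}.
#' @export
fitPca <- function(x, useCorrelation = FALSE) {
  if (is(x, "IndicatorSet")) {
    if (!isNormalized(x))
      stop("fitPca expects a normalized IndicatorSet")
    x <- indicatorMatrix(x)$x
  }
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  if (nrow(x) < ncol(x) + 1L)
    stop("fewer land cells (", nrow(x), ") than indicators + 1")
  cv <- if (useCorrelation) stats::cor(x) else stats::cov(x)
  if (any(!is.finite(cv)))
    stop("non-finite covariance; check for degenerate indicator layers")
  e <- eigen(cv, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  new("PcaResult",
      loadings = e$vectors,
      eigenvalues = vals,
      contributions = vals / sum(vals),
      center = colMeans(x),
      oriented = FALSE,
      indicators = colnames(x) %||% paste0("V", seq_len(ncol(x))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compose the ecological index from a fitted PCA
#'
#' Projects land cells onto PC1, orients the scores so the index increases
#' with the greenness indicator (scores are negated when their Pearson
#' correlation with SAVI is negative — the deterministic counterpart of the
#' conditional 1 - PC1 convention), then min-max rescales to [0, 1].
#'
#' @param pca a \linkS4class{PcaResult} from \code{\link{fitPca}}.
#' @param indset the \linkS4class{IndicatorSet} the PCA was fitted on.
#' @param orientBy indicator the index must correlate positively with
#'   (default \code{"savi"}).
#' @return An \linkS4class{RseiResult}.
#' @export
composeRsei <- function(pca, indset, orientBy = "savi") {
  im <- indicatorMatrix(indset)
  x <- im$x
  stopifnot(orientBy %in% colnames(x))
  score <- as.vector(scale(x, center = pca@center, scale = FALSE) %*%
                     pca@loadings[, 1L])
  if (stats::sd(score) == 0)
    stop("degenerate PC1 score field (constant)")
  oriented <- FALSE
  if (stats::cor(score, x[, orientBy]) < 0) {
    score <- -score
    oriented <- TRUE
  }
  rs <- (score - min(score)) / (max(score) - min(score))
  tmpl <- gridValues(indset@layers[[1L]])
  vals <- matrix(NA_real_, nrow(tmpl), ncol(tmpl))
  vals[im$idx] <- rs
  rsei <- setGridValues(indset@layers[[1L]], vals)
  classes <- classifyRsei(rsei)
  pca@oriented <- oriented
  new("RseiResult",
      rsei = rsei,
      classes = classes,
      pca = pca,
      classAreas = classAreaStats(classes),
      indicatorCorrelations = apply(x, 2L, stats::cor, y = rs))
}

#' One-call index computation
#'
#' @param indset a normalized \linkS4class{IndicatorSet}.
#' @param ... passed to \code{\link{fitPca}} and \code{\link{composeRsei}}.
#' @return An \linkS4class{RseiResult}.
#' @export
computeRsei <- function(indset, ...) {
  composeRsei(fitPca(indset), indset, ...)
}

#' Grade the index into five ecological-quality classes
#'
#' Class I (bad) [0, 0.20), II (poor) [0.20, 0.40), III (moderate)
#' [0.40, 0.60), IV (good) [0.60, 0.80), V (excellent) [0.80, 1]; lower
#' bounds inclusive, top bound closed.
#'
#' @param rsei \linkS4class{RasterGrid} with values in [0, 1].
#' @return Integer-valued \linkS4class{RasterGrid} with codes 1..5.
#' @export
classifyRsei <- function(rsei) {
  v <- gridValues(rsei)
  ok <- !is.na(v)
  if (any(v[ok] < -1e-12 | v[ok] > 1 + 1e-12))
    stop("index values outside [0, 1]; classify after rescaling")
  cls <- matrix(NA_real_, nrow(v), ncol(v))
  cls[ok] <- findInterval(v[ok], c(0.20, 0.40, 0.60, 0.80)) + 1
  setGridValues(rsei, cls)
}

#' Labels of the five index grades
#' @return character vector of length 5 (codes 1..5).
#' @export
rseiClassLabels <- function() .rseiClassLabels

#' Per-class cell counts and areas
#'
#' Equal-area accounting on the projected grid: area of a class =
#' cell count x cell_size^2 (reported in km^2); percentages are of the
#' unmasked (land) cells.
#'
#' @param classes integer-valued class \linkS4class{RasterGrid}.
#' @return data.frame: class, label, cells, area_km2, percent.
#' @export
classAreaStats <- function(classes) {
  v <- gridValues(classes)
  ok <- !is.na(v)
  n <- sum(ok)
  if (n == 0L) stop("no unmasked cells")
  cellKm2 <- (cellSize(classes) / 1000)^2
  counts <- tabulate(v[ok], nbins = 5L)
  data.frame(
    class = 1:5,
    label = .rseiClassLabels,
    cells = counts,
    area_km2 = counts * cellKm2,
    percent = 100 * counts / n)
}

#' Pearson correlation between two aligned grids
#'
#' Computed over the jointly unmasked cells.
#'
#' @param a,b aligned \linkS4class{RasterGrid}s.
#' @return Pearson r.
#' @export
rasterCorrelation <- function(a, b) {
  assertAligned(list(a, b), "correlation inputs")
  x <- as.vector(gridValues(a)); y <- as.vector(gridValues(b))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) stop("fewer than 3 jointly unmasked cells")
  stats::cor(x[ok], y[ok])
}

#' Loading / contribution report for an index result
#'
#' One row per principal component with its eigenvalue, contribution rate
#' and indicator loadings — the per-epoch PCA summary table.
#'
#' @param res an \linkS4class{RseiResult}.
#' @return data.frame.
#' @export
pcaReport <- function(res) {
  pca <- rseiPca(res)
  p <- length(pca@indicators)
  out <- data.frame(
    component = paste0("PC", seq_len(p)),
    eigenvalue = pca@eigenvalues,
    contribution_pct = 100 * pca@contributions)
  ld <- t(pca@loadings)
  colnames(ld) <- paste0("loading_", pca@indicators)
  cbind(out, as.data.frame(ld))
}
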