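# Multi-epoch dynamics: change-vector grading of the five index classes,
# FROM-TO transition accounting, coefficient-of-variation stability levels,
# and rescaled-range (R/S) Hurst persistence mapping.

.hurstClassLabels <- c("strong antisustainability", "weak antisustainability",
                       "weak sustainability", "strong sustainability")

#' Labels of the five change types
#' @return character vector (codes 1..5: deteriorated significantly,
#'   deteriorated, unchanged, improved, improved significantly).
#' @export
changeTypeLabels <- function() .changeTypeLabels

#' Labels of the four Hurst persistence classes
#' @return character vector (codes 1..4).
#' @export
hurstClassLabels <- function() .hurstClassLabels

.checkClassGrid <- function(g, what) {
  v <- gridValues(g)
  ok <- !is.na(v)
  if (any(v[ok] < 1 | v[ok] > 5 | v[ok] != round(v[ok])))
    stop(what, " must hold integer class codes 1..5")
  invisible(TRUE)
}

#' Grade change between two classified epochs
#'
#' Change-vector analysis on ordinal grades: delta = class(t2) - class(t1),
#' in [-4, 4], binned into five change types: [-4, -2] deteriorated
#' significantly, -1 deteriorated, 0 unchanged, 1 improved, [2, 4] improved
#' significantly. Cells masked in either epoch are masked.
#'
#' @param classesT1,classesT2 aligned class \linkS4class{RasterGrid}s
#'   (codes 1..5).
#' @return list with \code{deltaGrade} and \code{changeType} grids.
#' @export
changeGrade <- function(classesT1, classesT2) {
  assertAligned(list(classesT1, classesT2), "class rasters")
  .checkClassGrid(classesT1, "epoch-1 classes")
  .checkClassGrid(classesT2, "epoch-2 classes")
  d <- gridValues(classesT2) - gridValues(classesT1)
  type <- d
  ok <- !is.na(d)
  type[ok] <- findInterval(d[ok], c(-1.5, -0.5, 0.5, 1.5)) + 1
  list(deltaGrade = setGridValues(classesT1, d),
       changeType = setGridValues(classesT1, type))
}

#' FROM-TO class transition table
#'
#' Cross-tabulates class membership between two epochs over the jointly
#' unmasked cells, including unchanged (diagonal) pairs, with equal-area
#' km^2 and percent-of-land accounting.
#'
#' @param classesT1,classesT2 aligned class grids (codes 1..5).
#' @return data.frame: from, to, cells, area_km2, percent.
#' @export
transitionMatrix <- function(classesT1, classesT2) {
  assertAligned(list(classesT1, classesT2), "class rasters")
  .checkClassGrid(classesT1, "epoch-1 classes")
  .checkClassGrid(classesT2, "epoch-2 classes")
  a <- as.vector(gridValues(classesT1)); b <- as.vector(gridValues(classesT2))
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no jointly unmasked cells")
  tab <- table(from = a[ok], to = b[ok])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0L, ]
  cellKm2 <- (cellSize(classesT1) / 1000)^2
  out <- data.frame(
    from = as.integer(df$from),
    to = as.integer(df$to),
    cells = df$Freq,
    area_km2 = df$Freq * cellKm2,
    percent = 100 * df$Freq / sum(ok))
  out[order(out$from, out$to), ]
}

#' Build a ChangeSummary for an epoch pair
#'
#' @param classesT1,classesT2 aligned class grids.
#' @return A \linkS4class{ChangeSummary}.
#' @export
changeSummary <- function(classesT1, classesT2) {
  cg <- changeGrade(classesT1, classesT2)
  new("ChangeSummary", deltaGrade = cg$deltaGrade,
      changeType = cg$changeType,
      transitions = transitionMatrix(classesT1, classesT2))
}

#' Per-cell coefficient of variation across epochs
#'
#' CV = population standard deviation / mean per cell (default), or the
#' mean-absolute-deviation variant CV = mean|x - mean| / mean
#' (\code{estimator = "mad"}). Binned into five stability levels at the
#' fixed breakpoints 0.10 / 0.20 / 0.30 / 0.40 (CV above 1 stays level 5).
#' Cells with nonpositive mean, or masked in any epoch, are masked.
#'
#' @param series list of aligned index \linkS4class{RasterGrid}s in epoch
#'   order (length >= 3).
#' @param estimator \code{"sd"} (default) or \code{"mad"}.
#' @return list with \code{cv} and \code{cvLevel} grids.
#' @export
coefficientOfVariation <- function(series, estimator = c("sd", "mad")) {
  estimator <- match.arg(estimator)
  if (length(series) < 3L) stop("need at least 3 epochs for CV")
  assertAligned(series, "CV input series")
  arr <- vapply(series, function(g) as.vector(gridValues(g)),
                numeric(length(gridValues(series[[1L]]))))
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1L)
  mu <- rowMeans(arr)
  disp <- if (estimator == "sd") {
    sqrt(rowMeans((arr - mu)^2))
  } else {
    rowMeans(abs(arr - mu))
  }
  cv <- disp / mu
  cv[is.na(mu) | !is.na(mu) & mu <= 0] <- NA_real_
  lvl <- ifelse(is.na(cv), NA_real_,
                pmin(findInterval(cv, c(0.10, 0.20, 0.30, 0.40)) + 1, 5))
  shp <- dim(gridValues(series[[1L]]))
  list(cv = setGridValues(series[[1L]], matrix(cv, shp[1L], shp[2L])),
       cvLevel = setGridValues(series[[1L]], matrix(lvl, shp[1L], shp[2L])))
}

#' Rescaled-range Hurst exponent of a numeric series
#'
#' Classical R/S estimation: for each window length tau, the series is cut
#' into floor(n/tau) non-overlapping segments; each segment contributes
#' R/S = (range of cumulative mean-adjusted sums) / (population standard
#' deviation), zero-sd segments are skipped; mean R/S per tau is regressed
#' as log(R/S) ~ log(tau) and the slope is H, clipped to (0, 1].
#'
#' @param x numeric series (epochs in order), length >= 8.
#' @param taus window lengths (default all integers 2..floor(n/2)).
#' @return H, or NA if fewer than 3 valid (tau, mean R/S) points remain.
#' @export
hurstRS <- function(x, taus = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) return(NA_real_)
  if (is.null(taus)) taus <- 2:(n %/% 2L)
  taus <- taus[taus >= 2L & taus <= n]
  pts <- vapply(taus, function(tau) {
    m <- n %/% tau
    rs <- vapply(seq_len(m), function(j) {
      z <- x[((j - 1L) * tau + 1L):(j * tau)]
      s <- sqrt(mean((z - mean(z))^2))
      if (s == 0) return(NA_real_)
      cumdev <- cumsum(z - mean(z))
      (max(cumdev) - min(cumdev)) / s
    }, numeric(1L))
    rs <- rs[!is.na(rs) & rs > 0]
    if (length(rs)) mean(rs) else NA_real_
  }, numeric(1L))
  keep <- !is.na(pts) & pts > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- stats::lm.fit(cbind(1, log(taus[keep])), log(pts[keep]))
  h <- unname(fit$coefficients[2L])
  # estimates outside (0, 1] are finite-sample artifacts; clip
  min(max(h, 1e-3), 1)
}

#' Per-cell Hurst exponent map
#'
#' Applies \code{\link{hurstRS}} to each cell's epoch series and classifies
#' H into the four persistence classes: strong antisustainability
#' [0, 0.35), weak antisustainability [0.35, 0.50), weak sustainability
#' [0.50, 0.65), strong sustainability [0.65, 1].
#'
#' @param series list of aligned index grids in epoch order (length >= 8).
#' @param taus window lengths passed to \code{\link{hurstRS}}.
#' @return list with \code{hurst} and \code{hurstClass} grids.
#' @export
hurstExponent <- function(series, taus = NULL) {
  if (length(series) < 8L) stop("need at least 8 epochs for the Hurst map")
  assertAligned(series, "Hurst input series")
  arr <- vapply(series, function(g) as.vector(gridValues(g)),
                numeric(length(gridValues(series[[1L]]))))
  if (is.null(dim(arr))) arr <- matrix(arr, nrow = 1L)
  h <- apply(arr, 1L, function(x) {
    if (anyNA(x)) return(NA_real_)
    hurstRS(x, taus = taus)
  })
  cls <- classifyHurst(h)
  shp <- dim(gridValues(series[[1L]]))
  list(hurst = setGridValues(series[[1L]], matrix(h, shp[1L], shp[2L])),
       hurstClass = setGridValues(series[[1L]], matrix(cls, shp[1L], shp[2L])))
}

#' Classify Hurst exponents into the four persistence classes
#' @param h numeric vector of H values.
#' @return integer codes 1..4 (see \code{\link{hurstClassLabels}}), NA kept.
#' @export
classifyHurst <- function(h) {
  out <- rep(NA_real_, length(h))
  ok <- !is.na(h)
  out[ok] <- findInterval(h[ok], c(0.35, 0.50, 0.65)) + 1
  out
}

#' Stability and persistence maps for an index series
#'
#' @param series list of aligned index grids in epoch order.
#' @param estimator CV estimator, see \code{\link{coefficientOfVariation}}.
#' @param taus Hurst window lengths, see \code{\link{hurstRS}}.
#' @return A \linkS4class{StabilityPersistence}.
#' @export
stabilityPersistence <- function(series, estimator = "sd", taus = NULL) {
  cv <- coefficientOfVariation(series, estimator = estimator)
  hu <- hurstExponent(series, taus = taus)
  new("StabilityPersistence", cv = cv$cv, cvLevel = cv$cvLevel,
      hurst = hu$hurst, hurstClass = hu$hurstClass)
}
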