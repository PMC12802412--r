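# Optimal-parameter geographical detector.
#
# The q-statistic measures how much a stratification of a driver factor
# explains the spatial variance of the response: q = 1 - SSW/SST, where SSW
# sums squared deviations from stratum means and SST from the global mean
# (equivalently 1 - sum(N_h sigma_h^2) / (N sigma^2) with population
# variances). Each continuous factor is discretized by five methods over a
# range of class counts and the (method, k) pair maximizing q is retained;
# factor significance comes from a seeded permutation test and pairwise
# interactions from the q of the product stratification.

.opgdMethods <- c("equal_interval", "natural_breaks", "quantile",
                  "geometric", "std_dev")

#' Names of the supported discretization methods, in selection-priority order
#' @return character vector of length 5.
#' @export
opgdMethods <- function() .opgdMethods

#' Geographical-detector q-statistic
#'
#' q = 1 - SSW/SST over the samples with both y and stratum present
#' (listwise deletion). Single-sample strata contribute zero to SSW.
#'
#' @param y numeric response vector.
#' @param strata stratum labels (any type coercible to factor).
#' @return q in [0, 1].
#' @export
qStatistic <- function(y, strata) {
  ok <- !is.na(y) & !is.na(strata)
  y <- y[ok]; strata <- strata[ok]
  if (length(y) < 2L) stop("need at least 2 samples")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("degenerate response: total sum of squares is 0")
  ssw <- sum(vapply(split(y, strata), function(g) sum((g - mean(g))^2),
                    numeric(1L)))
  1 - ssw / sst
}

#' Discretize a continuous factor
#'
#' Five break-selection methods over the finite values of \code{x}:
#' \describe{
#'   \item{equal_interval}{breaks at min + i (max - min)/k.}
#'   \item{natural_breaks}{Fisher-Jenks dynamic program minimizing the
#'     within-class sum of squares over contiguous value-ordered classes;
#'     exact for n <= 10000, above that the DP runs on 10000 evenly spaced
#'     order statistics (deterministic).}
#'   \item{quantile}{breaks at the i/k empirical quantiles (type 7),
#'     duplicates merged.}
#'   \item{geometric}{geometric progression of interval widths,
#'     b_i = min + (max - min)(g^i - 1)/(g^k - 1) with multiplier g.}
#'   \item{std_dev}{interior breaks at mean + f s (i - k/2), i = 1..k-1,
#'     clamped to the data range, duplicates merged.}
#' }
#' Samples are labelled by half-open bins [b_{i-1}, b_i), top bin closed.
#' When merging leaves fewer classes than requested the realized k is
#' reported with a warning.
#'
#' @param x numeric vector (non-finite values get NA labels).
#' @param method one of \code{\link{opgdMethods}}.
#' @param k requested class count (>= 2).
#' @param g geometric multiplier (default 2).
#' @param f std-dev step factor (default 0.5).
#' @return A \linkS4class{Discretization} (q slot NA).
#' @export
discretize <- function(x, method = .opgdMethods, k, g = 2, f = 0.5) {
  method <- match.arg(method)
  stopifnot(k >= 2L)
  fin <- is.finite(x)
  xf <- x[fin]
  if (length(unique(xf)) < 2L) stop("factor has fewer than 2 distinct values")
  lo <- min(xf); hi <- max(xf)
  breaks <- switch(method,
    equal_interval = lo + seq_len(k - 1L) * (hi - lo) / k,
    quantile = unname(stats::quantile(xf, probs = seq_len(k - 1L) / k,
                                      type = 7)),
    natural_breaks = .jenksBreaks(xf, k),
    geometric = lo + (hi - lo) * (g^seq_len(k - 1L) - 1) / (g^k - 1),
    std_dev = {
      m <- mean(xf); s <- stats::sd(xf)
      b <- m + f * s * (seq_len(k - 1L) - k / 2)
      b[b > lo & b < hi]
    })
  breaks <- sort(unique(breaks))
  breaks <- breaks[breaks > lo & breaks < hi]
  realized <- length(breaks) + 1L
  if (realized < k && method != "std_dev")
    warning("realized only ", realized, " classes for ", method,
            " (requested ", k, ")")
  labels <- rep(NA_integer_, length(x))
  labels[fin] <- findInterval(xf, breaks) + 1L
  new("Discretization", method = method, k = realized,
      breaks = as.numeric(breaks), labels = as.integer(labels),
      q = NA_real_)
}

# Fisher-Jenks interior breaks; each cut point is the midpoint between the
# last element of a class and the first element of the next, so half-open
# [b_{i-1}, b_i) labelling reproduces the DP partition on distinct values.
.jenksBreaks <- function(xf, k) {
  xs <- sort(xf)
  n <- length(xs)
  if (n > 10000L) xs <- xs[round(seq(1L, n, length.out = 10000L))]
  k <- min(k, length(unique(xs)))
  res <- .fisherJenksCpp(xs, as.integer(k))
  starts <- res$starts[-1L] + 1L
  unique((xs[starts] + xs[starts - 1L]) / 2)
}

#' Pick the q-maximizing (method, k) discretization of a factor
#'
#' Evaluates q for every (method, class-count) combination and returns the
#' argmax; ties go to the smaller k, then to the method listed first in
#' \code{\link{opgdMethods}}.
#'
#' @param y numeric response.
#' @param x numeric continuous factor.
#' @param methods subset of \code{\link{opgdMethods}}.
#' @param kRange candidate class counts (default 5:10).
#' @return A \linkS4class{Discretization} with its q filled in.
#' @export
optimalDiscretization <- function(y, x, methods = .opgdMethods,
                                  kRange = 5:10) {
  methods <- match.arg(methods, .opgdMethods, several.ok = TRUE)
  best <- NULL
  for (k in sort(kRange)) {
    for (m in methods) {
      d <- tryCatch(suppressWarnings(discretize(x, m, k)),
                    error = function(e) NULL)
      if (is.null(d) || d@k < 2L) next
      qv <- tryCatch(qStatistic(y, d@labels), error = function(e) NA_real_)
      if (is.na(qv)) next
      d@q <- qv
      if (is.null(best) || qv > best@q + 1e-15) best <- d
    }
  }
  if (is.null(best)) stop("no admissible discretization found")
  best
}

#' Diagnostic q surface over (method, k)
#'
#' The per-factor selection diagnostic: q for every method and class count.
#'
#' @inheritParams optimalDiscretization
#' @return data.frame: method, k, q (NA where inadmissible).
#' @export
discretizationScan <- function(y, x, methods = .opgdMethods, kRange = 5:10) {
  grid <- expand.grid(method = methods, k = sort(kRange),
                      stringsAsFactors = FALSE)
  grid$q <- vapply(seq_len(nrow(grid)), function(i) {
    d <- tryCatch(suppressWarnings(discretize(x, grid$method[i], grid$k[i])),
                  error = function(e) NULL)
    if (is.null(d) || d@k < 2L) return(NA_real_)
    tryCatch(qStatistic(y, d@labels), error = function(e) NA_real_)
  }, numeric(1L))
  grid
}

#' Sample aligned rasters on a regular grid
#'
#' Takes every \code{spacing}-th cell in both axes (the regular grid-unit
#' sampling used for driver analysis), dropping cells masked in the
#' response raster.
#'
#' @param rasters named list of aligned \linkS4class{RasterGrid}s; the first
#'   (or one named \code{"response"}) is the response.
#' @param spacing cell stride (>= 1).
#' @return data.frame with columns row, col, x, y (map coordinates), one
#'   column per raster.
#' @export
sampleGrid <- function(rasters, spacing = 1L) {
  stopifnot(spacing >= 1L, length(rasters) >= 1L)
  assertAligned(rasters, "sampling rasters")
  respName <- if ("response" %in% names(rasters)) "response" else
    names(rasters)[1L]
  ref <- rasters[[1L]]
  d <- dim(gridValues(ref))
  rows <- seq(1L, d[1L], by = spacing)
  cols <- seq(1L, d[2L], by = spacing)
  idx <- as.matrix(expand.grid(row = rows, col = cols))
  tr <- gridTransform(ref); cs <- tr[[3L]]
  out <- data.frame(
    row = idx[, "row"], col = idx[, "col"],
    x = tr[[1L]] + (idx[, "col"] - 0.5) * cs,
    y = tr[[2L]] - (idx[, "row"] - 0.5) * cs)
  for (nm in names(rasters))
    out[[nm]] <- gridValues(rasters[[nm]])[idx]
  keep <- !is.na(out[[respName]])
  if (!any(keep)) stop("no valid sample points")
  out[keep, , drop = FALSE]
}

#' Factor detector with optimal discretization
#'
#' Per factor: continuous factors get their q-maximizing discretization,
#' categorical factors are used as-is; significance is a seeded permutation
#' test, p = (1 + #[q_perm >= q_obs]) / (1 + nPerm), permuting y with the
#' strata fixed. The table is sorted by q descending.
#'
#' @param y numeric response at the sample points.
#' @param factors named list of factor vectors (numeric = continuous;
#'   factor/character/logical = categorical).
#' @param kRange class counts scanned for continuous factors (default 5:10).
#' @param methods discretization methods scanned (default all five).
#' @param nPerm permutation count (default 999; 0 skips the test, p = NA).
#' @param seed integer seed for the permutation draws.
#' @return list with \code{table} (data.frame: factor, method, k, q,
#'   p_value) and \code{strata} (named list of per-factor label vectors).
#' @export
factorDetector <- function(y, factors, kRange = 5:10,
                           methods = .opgdMethods, nPerm = 999, seed = 1L) {
  stopifnot(length(factors) >= 1L, !is.null(names(factors)))
  rows <- list(); strata <- list()
  for (nm in names(factors)) {
    xv <- factors[[nm]]
    if (is.numeric(xv) && length(unique(xv[is.finite(xv)])) > 2L) {
      d <- tryCatch(optimalDiscretization(y, xv, methods, kRange),
                    error = function(e) NULL)
      if (is.null(d)) {
        rows[[nm]] <- data.frame(factor = nm, method = NA, k = NA,
                                 q = NA_real_, p_value = NA_real_)
        next
      }
      lab <- d@labels; meth <- d@method; kk <- d@k; qv <- d@q
    } else {
      lab <- as.integer(factor(xv))
      if (length(unique(lab[!is.na(lab)])) < 2L) {
        rows[[nm]] <- data.frame(factor = nm, method = "categorical",
                                 k = NA, q = NA_real_, p_value = NA_real_)
        next
      }
      meth <- "categorical"; kk <- length(unique(lab[!is.na(lab)]))
      qv <- qStatistic(y, lab)
    }
    p <- NA_real_
    if (nPerm > 0) {
      ok <- !is.na(y) & !is.na(lab)
      yy <- y[ok]; ll <- lab[ok]
      set.seed(seed + match(nm, names(factors)))
      hits <- 0L
      for (b in seq_len(nPerm))
        if (qStatistic(sample(yy), ll) >= qv - 1e-12) hits <- hits + 1L
      p <- (1 + hits) / (1 + nPerm)
    }
    rows[[nm]] <- data.frame(factor = nm, method = meth, k = kk, q = qv,
                             p_value = p)
    strata[[nm]] <- lab
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(-ifelse(is.na(tab$q), -Inf, tab$q)), ]
  list(table = tab, strata = strata)
}

#' Interaction detector for a factor pair
#'
#' q of the cartesian-product stratification of the two label vectors
#' (empty combinations drop out), categorized against the marginal q values:
#' nonlinear weaken (q_ij < min), single-factor weaken (min <= q_ij < max),
#' bi-factor enhance (max <= q_ij < q_i + q_j), independent
#' (q_ij = q_i + q_j), nonlinear enhance (q_ij > q_i + q_j).
#'
#' @param y numeric response.
#' @param strataI,strataJ stratum label vectors of the two factors.
#' @param qI,qJ their marginal q values (computed if missing).
#' @return list: qIJ, category, qI, qJ.
#' @export
interactionDetector <- function(y, strataI, strataJ, qI = NULL, qJ = NULL) {
  if (is.null(qI)) qI <- qStatistic(y, strataI)
  if (is.null(qJ)) qJ <- qStatistic(y, strataJ)
  ok <- !is.na(strataI) & !is.na(strataJ)
  lab <- interaction(strataI[ok], strataJ[ok], drop = TRUE)
  if (nlevels(lab) < 2L) stop("product stratification has < 2 strata")
  qIJ <- qStatistic(y[ok], lab)
  lo <- min(qI, qJ); hi <- max(qI, qJ)
  category <-
    if (abs(qIJ - (qI + qJ)) <= 1e-9) "independent"
    else if (qIJ > qI + qJ) "nonlinear enhance"
    else if (qIJ >= hi) "bi-factor enhance"
    else if (qIJ >= lo) "single-factor weaken"
    else "nonlinear weaken"
  list(qIJ = qIJ, category = category, qI = qI, qJ = qJ)
}

#' Full optimal-parameter geographical detector run
#'
#' Factor detection on every declared factor, then interaction detection on
#' every factor pair, using each factor's optimal (or raw categorical)
#' stratification.
#'
#' @inheritParams factorDetector
#' @return An \linkS4class{OpgdResult}.
#' @export
opgdDetect <- function(y, factors, kRange = 5:10, methods = .opgdMethods,
                       nPerm = 999, seed = 1L) {
  fd <- factorDetector(y, factors, kRange, methods, nPerm, seed)
  nms <- names(fd$strata)
  pairs <- if (length(nms) >= 2L) utils::combn(nms, 2L, simplify = FALSE)
           else list()
  inter <- lapply(pairs, function(pr) {
    qi <- fd$table$q[fd$table$factor == pr[1L]]
    qj <- fd$table$q[fd$table$factor == pr[2L]]
    r <- interactionDetector(y, fd$strata[[pr[1L]]], fd$strata[[pr[2L]]],
                             qi, qj)
    data.frame(factor_i = pr[1L], factor_j = pr[2L], q_i = r$qI, q_j = r$qJ,
               q_ij = r$qIJ, category = r$category)
  })
  itab <- if (length(inter)) do.call(rbind, inter) else
    data.frame(factor_i = character(), factor_j = character(),
               q_i = numeric(), q_j = numeric(), q_ij = numeric(),
               category = character())
  rownames(itab) <- NULL
  new("OpgdResult", factorTable = fd$table, interactionTable = itab,
      discretizations = fd$strata)
}
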