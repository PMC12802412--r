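# Seeded synthetic-scene simulator.
#
# A smooth latent ecological-quality field E in [0, 1] drives the five
# reflectance bands with the same sign structure the index expects
# (greenness and moisture rise with E; bareness, salinity and temperature
# fall with E), so every pipeline stage can be validated against known
# ground truth without a satellite archive. All randomness comes from R's
# default Mersenne-Twister generator under the spec seed.

#' Specification of a synthetic scene
#'
#' @param shape integer (rows, cols) of the grid.
#' @param cellSize cell size in metres (default 500).
#' @param seed integer RNG seed; identical specs give bit-identical scenes.
#' @param smoothness correlation length of the latent field, in cells.
#' @param noiseSd per-band reflectance noise standard deviation.
#' @param waterFraction fraction of cells made open water (in [0, 0.5)).
#' @param trend per-epoch additive drift applied to the latent field.
#' @param epochs number of epochs for time-series simulation.
#' @param crs CRS tag stamped on the grids.
#' @return A list of class \code{sceneSpec}.
#' @export
sceneSpec <- function(shape = c(64L, 64L), cellSize = 500, seed = 1L,
                      smoothness = 8, noiseSd = 0.01, waterFraction = 0.05,
                      trend = 0, epochs = 12L, crs = "EPSG:32649") {
  stopifnot(length(shape) == 2L, all(shape >= 4L), cellSize > 0,
            smoothness > 0, noiseSd >= 0,
            waterFraction >= 0, waterFraction < 0.5, epochs >= 1L)
  structure(list(shape = as.integer(shape), cellSize = cellSize,
                 seed = as.integer(seed), smoothness = smoothness,
                 noiseSd = noiseSd, waterFraction = waterFraction,
                 trend = trend, epochs = as.integer(epochs), crs = crs),
            class = "sceneSpec")
}

# Smooth standard-normal field: white noise convolved with a Gaussian
# kernel separably in both axes (row-normalized smoothing matrices keep
# edges unbiased), then min-max scaled to [0, 1].
.gaussianField <- function(nr, nc, corrLen) {
  smoother <- function(n) {
    i <- seq_len(n)
    w <- outer(i, i, function(a, b) exp(-(a - b)^2 / (2 * corrLen^2)))
    w / rowSums(w)
  }
  field <- smoother(nr) %*% matrix(stats::rnorm(nr * nc), nr, nc) %*%
    t(smoother(nc))
  (field - min(field)) / (max(field) - min(field))
}

# Contiguous water blobs: union of disks around m seed centres, with the
# distance threshold chosen as the waterFraction quantile of the
# distance-to-nearest-centre field so the realized fraction is exact.
.waterBlobs <- function(nr, nc, fraction) {
  if (fraction <= 0) return(matrix(FALSE, nr, nc))
  m <- max(1L, round(nr * nc * fraction / 400))
  cr <- stats::runif(m, 1, nr)
  cc <- stats::runif(m, 1, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- matrix(Inf, nr, nc)
  for (j in seq_len(m))
    d <- pmin(d, sqrt((rows - cr[j])^2 + (cols - cc[j])^2))
  d <= stats::quantile(d, fraction)
}

# Band model: linear responses to E with additive Gaussian noise, clipped
# to the physically plausible reflectance window.
.bandCoefs <- list(
  b1 = c(0.25, -0.15),  # red: brighter soil when quality is low
  b2 = c(0.10,  0.40),  # NIR: rises with vegetation
  b4 = c(0.12, -0.04),  # green
  b6 = c(0.35, -0.20),  # SWIR1: drier surfaces are brighter
  b7 = c(0.28, -0.18))  # SWIR2

.lstT0 <- 18; .lstDT <- 20  # degrees C: LST = T0 + DT (1 - E)

.makeStack <- function(E, water, spec, epoch) {
  nr <- nrow(E); nc <- ncol(E)
  tr <- c(0, nr * spec$cellSize, spec$cellSize)
  mkGrid <- function(v) RasterGrid(v, tr, spec$crs)
  bands <- lapply(.bandCoefs, function(cf) {
    v <- cf[1L] + cf[2L] * E + stats::rnorm(nr * nc, 0, spec$noiseSd)
    pmin(pmax(v, 0.01), 0.95)
  })
  bands$b4[water] <- 0.30
  bands$b6[water] <- 0.05
  tC <- .lstT0 + .lstDT * (1 - E) +
    stats::rnorm(nr * nc, 0, spec$noiseSd * 20)
  dn <- (tC + 273.15) / 0.02
  BandStack(lapply(bands, mkGrid), mkGrid(dn), epoch = epoch)
}

#' Simulate one synthetic band stack with ground truth
#'
#' The latent quality field E is smoothed Gaussian noise rescaled to [0, 1];
#' reflectance bands respond linearly to E (noise \code{noiseSd}, clipped to
#' [0.01, 0.95]); LST digital numbers encode 18 + 20 (1 - E) degrees C; and
#' contiguous water blobs override the green/SWIR1 bands so MNDWI masking
#' finds them.
#'
#' @param spec a \code{\link{sceneSpec}}.
#' @return list: \code{stack} (\linkS4class{BandStack}), \code{truth}
#'   (list with \code{latent} grid, \code{waterMask}, \code{spec}).
#' @export
simulateScene <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"))
  set.seed(spec$seed)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  E <- .gaussianField(nr, nc, spec$smoothness)
  water <- .waterBlobs(nr, nc, spec$waterFraction)
  stack <- .makeStack(E, water, spec, epoch = "epoch1")
  tr <- c(0, nr * spec$cellSize, spec$cellSize)
  list(stack = stack,
       truth = list(latent = RasterGrid(E, tr, spec$crs),
                    waterMask = water, spec = spec))
}

#' Simulate a multi-epoch time series of band stacks
#'
#' Epoch t (t = 0, 1, ...) uses latent field clip(E + t trend, 0, 1); a
#' negative trend produces monotone degradation. The water mask is shared
#' across epochs; per-epoch band noise is drawn from seeds derived from the
#' spec seed.
#'
#' @param spec a \code{\link{sceneSpec}} with \code{epochs >= 3}.
#' @return list: \code{stacks} (list of \linkS4class{BandStack}),
#'   \code{truth} (latent grids per epoch, waterMask, spec).
#' @export
simulateTimeseries <- function(spec) {
  stopifnot(inherits(spec, "sceneSpec"), spec$epochs >= 3L)
  set.seed(spec$seed)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  E0 <- .gaussianField(nr, nc, spec$smoothness)
  water <- .waterBlobs(nr, nc, spec$waterFraction)
  tr <- c(0, nr * spec$cellSize, spec$cellSize)
  stacks <- vector("list", spec$epochs)
  latents <- vector("list", spec$epochs)
  for (t in seq_len(spec$epochs)) {
    Et <- pmin(pmax(E0 + (t - 1L) * spec$trend, 0), 1)
    set.seed(spec$seed + 1000L * t)
    stacks[[t]] <- .makeStack(Et, water, spec, epoch = sprintf("epoch%d", t))
    latents[[t]] <- RasterGrid(Et, tr, spec$crs)
  }
  list(stacks = stacks,
       truth = list(latent = latents, waterMask = water, spec = spec))
}

#' Simulate a driver raster with a known population q
#'
#' Strata are k quantile bins of the latent field; the validation response
#' is y = mu_d + e with stratum means mu_d equal to bin-midpoint quality and
#' noise variance sigma^2 = VarBetween (1 - q0) / q0, so the population
#' q-statistic of y given the driver strata equals \code{targetQ}.
#'
#' @param E latent-field \linkS4class{RasterGrid}.
#' @param k stratum count (>= 2).
#' @param targetQ target population q in (0, 1).
#' @param seed integer seed for the response noise.
#' @param continuous if TRUE the emitted driver raster is a continuous
#'   proxy (bin midpoints plus small jitter) instead of integer strata.
#' @return list: \code{driver} grid, \code{response} grid,
#'   \code{strata} (integer matrix), \code{targetQ}.
#' @export
simulateDriver <- function(E, k = 5L, targetQ = 0.8, seed = 1L,
                           continuous = FALSE) {
  stopifnot(targetQ > 0, targetQ < 1, k >= 2L)
  v <- gridValues(E)
  ok <- !is.na(v)
  if (length(unique(v[ok])) < k) stop("degenerate latent field")
  set.seed(seed)
  qs <- stats::quantile(v[ok], probs = seq_len(k - 1L) / k, type = 7)
  lab <- matrix(NA_integer_, nrow(v), ncol(v))
  lab[ok] <- findInterval(v[ok], qs) + 1L
  mids <- (seq_len(k) - 0.5) / k
  mu <- matrix(NA_real_, nrow(v), ncol(v))
  mu[ok] <- mids[lab[ok]]
  varBetween <- mean((mu[ok] - mean(mu[ok]))^2)
  sigma <- sqrt(varBetween * (1 - targetQ) / targetQ)
  y <- mu
  y[ok] <- mu[ok] + stats::rnorm(sum(ok), 0, sigma)
  driver <- if (continuous) {
    d <- mu
    d[ok] <- mu[ok] + stats::runif(sum(ok), -0.2 / k, 0.2 / k)
    d
  } else {
    storage.mode(lab) <- "double"
    lab
  }
  list(driver = setGridValues(E, driver),
       response = setGridValues(E, y),
       strata = lab, targetQ = targetQ)
}
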