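# Shared fixture builders: tiny grids and band stacks constructed in code.

makeGrid <- function(values, nr = NULL, nc = NULL,
                     transform = NULL, crs = "EPSG:32649") {
  if (!is.matrix(values)) values <- matrix(values, nr, nc)
  if (is.null(transform)) transform <- c(0, nrow(values) * 500, 500)
  RasterGrid(values, transform, crs)
}

# Band stack from per-band constant or matrix values on a common grid.
makeStack <- function(b1, b2, b4, b6, b7, lstDn = 14000, nr = 2L, nc = 2L,
                      epoch = "t") {
  up <- function(v) {
    if (is.matrix(v)) v else matrix(v, nr, nc)
  }
  g <- function(v) makeGrid(up(v))
  BandStack(list(b1 = g(b1), b2 = g(b2), b4 = g(b4), b6 = g(b6), b7 = g(b7)),
            g(lstDn), epoch = epoch)
}

# A small land-only scene whose bands respond monotonically to a gradient,
# giving a well-conditioned 5-indicator covariance.
gradientStack <- function(nr = 10L, nc = 10L, seed = 1L, noise = 0.002) {
  set.seed(seed)
  E <- matrix(seq(0, 1, length.out = nr * nc), nr, nc)
  jit <- function() matrix(rnorm(nr * nc, 0, noise), nr, nc)
  makeStack(
    b1 = 0.25 - 0.15 * E + jit(),
    b2 = 0.10 + 0.40 * E + jit(),
    b4 = 0.12 - 0.04 * E + jit(),
    b6 = 0.35 - 0.20 * E + jit(),
    b7 = 0.28 - 0.18 * E + jit(),
    lstDn = ((18 + 20 * (1 - E) + 273.15) / 0.02),
    nr = nr, nc = nc)
}

# Exhaustive contiguous-partition minimizer (oracle for Fisher-Jenks).
bruteJenks <- function(x, k) {
  xs <- sort(x)
  n <- length(xs)
  ssw <- function(v) sum((v - mean(v))^2)
  splits <- utils::combn(n - 1L, k - 1L, simplify = FALSE)
  best <- NULL
  for (sp in splits) {
    bounds <- c(0L, sp, n)
    tot <- sum(vapply(seq_len(k), function(i) {
      ssw(xs[(bounds[i] + 1L):bounds[i + 1L]])
    }, numeric(1L)))
    if (is.null(best) || tot < best$ssw - 1e-12) {
      best <- list(ssw = tot, starts = bounds[-(k + 1L)] + 1L)
    }
  }
  best$breaks <- xs[best$starts[-1L]]
  best
}

# Eq.-13 weighted-variance form of q (independent oracle for qStatistic).
qWeightedForm <- function(y, strata) {
  ok <- !is.na(y) & !is.na(strata)
  y <- y[ok]; strata <- strata[ok]
  N <- length(y)
  sigma2 <- mean((y - mean(y))^2)
  num <- sum(vapply(split(y, strata), function(g) {
    length(g) * mean((g - mean(g))^2)
  }, numeric(1L)))
  1 - num / (N * sigma2)
}
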