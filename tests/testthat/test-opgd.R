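test_that("q-statistic matches hand computations exactly", {
  expect_equal(qStatistic(c(1, 1, 3, 3), c("A", "A", "B", "B")), 1,
               tolerance = 1e-12)
  expect_equal(qStatistic(c(1, 3, 1, 3), c("A", "A", "B", "B")), 0,
               tolerance = 1e-12)
  expect_equal(qStatistic(c(1, 2, 3, 6), c("A", "A", "B", "B")), 9 / 14,
               tolerance = 1e-12)
  expect_error(qStatistic(c(2, 2, 2), c("A", "B", "A")), "degenerate")
})

test_that("sum-of-squares q equals the weighted-variance form and is affine-invariant", {
  set.seed(23)
  for (i in 1:100) {
    n <- sample(20:200, 1)
    y <- rnorm(n)
    strata <- sample(seq_len(sample(2:8, 1)), n, TRUE)
    q1 <- qStatistic(y, strata)
    expect_lt(abs(q1 - qWeightedForm(y, strata)), 1e-12)
    a <- runif(1, 0.5, 3); b <- rnorm(1)
    expect_lt(abs(qStatistic(a * y + b, strata) - q1), 1e-9)
    expect_gte(q1, 0); expect_lte(q1, 1)
  }
})

test_that("discretization methods produce the documented breaks", {
  x <- seq(0, 10, length.out = 101)
  d <- discretize(x, "equal_interval", 5)
  expect_equal(d@breaks, c(2, 4, 6, 8))

  d <- discretize(1:10, "quantile", 2)
  expect_equal(sum(d@labels == 1), 5)
  expect_equal(sum(d@labels == 2), 5)

  d <- discretize(c(1, 2, 3, 10, 11, 12), "natural_breaks", 2)
  expect_equal(d@labels, c(1L, 1L, 1L, 2L, 2L, 2L))

  d <- discretize(x, "geometric", 3, g = 2)
  expect_equal(d@breaks, c(10 * 1 / 7, 10 * 3 / 7), tolerance = 1e-12)

  d <- discretize(x, "std_dev", 4, f = 0.5)
  s <- sd(x)
  expect_equal(d@breaks, 5 + 0.5 * s * c(-1, 0, 1), tolerance = 1e-12)

  # degenerate bins merge with a warning and reduced realized k
  expect_warning(dd <- discretize(c(rep(1, 50), 2), "quantile", 5),
                 "realized")
  expect_lt(dd@k, 5)
  expect_error(discretize(rep(1, 10), "equal_interval", 3), "distinct")
})

test_that("Fisher-Jenks equals exhaustive enumeration on small arrays", {
  set.seed(77)
  for (i in 1:60) {
    n <- sample(6:12, 1)
    k <- sample(2:4, 1)
    x <- round(runif(n, 0, 100), 1)
    if (length(unique(x)) < k + 1) next
    oracle <- bruteJenks(x, k)
    d <- suppressWarnings(discretize(x, "natural_breaks", k))
    # recompute SSW from the labels
    ssw <- sum(tapply(x, d@labels, function(g) sum((g - mean(g))^2)))
    expect_equal(ssw, oracle$ssw, tolerance = 1e-9, info = paste(x, collapse = ","))
  }
})

test_that("optimal discretization maximizes q and breaks ties reproducibly", {
  set.seed(12)
  x <- c(rnorm(60, 0), rnorm(60, 8), rnorm(60, 16))
  y <- c(rnorm(60, 1, 0.1), rnorm(60, 2, 0.1), rnorm(60, 3, 0.1))
  best <- optimalDiscretization(y, x, methods = "natural_breaks",
                                kRange = 2:3)
  expect_equal(best@k, 3L)
  scan <- discretizationScan(y, x, methods = "natural_breaks", kRange = 2:3)
  expect_equal(best@q, max(scan$q, na.rm = TRUE), tolerance = 1e-12)

  # independent response: best q stays small at n = 1000
  set.seed(99)
  xN <- rnorm(1000); yN <- rnorm(1000)
  bestN <- optimalDiscretization(yN, xN)
  expect_lt(bestN@q, 0.05)

  single <- optimalDiscretization(y, x, methods = "quantile", kRange = 4)
  expect_identical(single@method, "quantile")
  expect_equal(single@k, 4L)
})

test_that("factor detector ranks factors and calibrates the permutation test", {
  set.seed(5)
  n <- 300
  y <- rnorm(n)
  det <- factorDetector(y, list(self = y, noise = rnorm(n)),
                        kRange = 10, methods = "quantile", nPerm = 99,
                        seed = 2)
  tab <- det$table
  expect_identical(tab$factor[1], "self")
  expect_gt(tab$q[tab$factor == "self"], 0.9)
  expect_equal(tab$p_value[tab$factor == "self"], 1 / 100)
  expect_gt(tab$p_value[tab$factor == "noise"], 0.05)

  # categorical factor matching the response groups exactly
  grp <- rep(c("a", "b", "c"), each = 20)
  yg <- rep(c(0, 5, 9), each = 20) + 0
  det2 <- factorDetector(yg, list(lucc = factor(grp)), nPerm = 0)
  expect_equal(det2$table$q, 1, tolerance = 1e-12)
  expect_identical(det2$table$method, "categorical")
})

test_that("interaction q refines both marginals; XOR is nonlinear enhance", {
  set.seed(3)
  for (i in 1:60) {
    n <- 150
    y <- rnorm(n)
    si <- sample(1:4, n, TRUE); sj <- sample(1:3, n, TRUE)
    r <- interactionDetector(y, si, sj)
    expect_gte(r$qIJ, max(r$qI, r$qJ) - 1e-12)
  }
  # XOR: y determined only by the pair
  a <- rep(c(0, 0, 1, 1), 25); b <- rep(c(0, 1, 0, 1), 25)
  y <- as.numeric(xor(a, b))
  r <- interactionDetector(y, a + 1, b + 1)
  expect_equal(r$qI, 0, tolerance = 1e-12)
  expect_equal(r$qJ, 0, tolerance = 1e-12)
  expect_equal(r$qIJ, 1, tolerance = 1e-12)
  expect_identical(r$category, "nonlinear enhance")

  # duplicated factor: q_ij = q_i, boundary classified as bi-factor enhance
  set.seed(10)
  yy <- rnorm(100); ss <- sample(1:5, 100, TRUE)
  dup <- interactionDetector(yy, ss, ss)
  expect_equal(dup$qIJ, dup$qI, tolerance = 1e-12)
  expect_identical(dup$category, "bi-factor enhance")
})

test_that("regular-grid sampling respects spacing and masks", {
  v <- matrix(runif(16), 4, 4)
  r <- makeGrid(v)
  s <- sampleGrid(list(response = r), spacing = 2)
  expect_equal(nrow(s), 4L)
  sAll <- sampleGrid(list(response = r), spacing = 1)
  expect_equal(nrow(sAll), 16L)

  vc <- v; vc[(row(vc) + col(vc)) %% 2 == 0] <- NA  # checkerboard
  sc <- sampleGrid(list(response = makeGrid(vc)), spacing = 1)
  expect_equal(nrow(sc), sum(!is.na(vc)))
  expect_error(sampleGrid(list(response = makeGrid(matrix(NA_real_, 2, 2)))),
               "no valid sample")
})

test_that("full detector run returns consistent factor and interaction tables", {
  sim <- simulateScene(sceneSpec(shape = c(40, 40), seed = 9,
                                 waterFraction = 0))
  drvA <- simulateDriver(sim$truth$latent, k = 5, targetQ = 0.7, seed = 2,
                         continuous = TRUE)
  set.seed(4)
  noise <- setGridValues(sim$truth$latent,
                         matrix(rnorm(1600), 40, 40))
  samp <- sampleGrid(list(response = drvA$response, npp = drvA$driver,
                          junk = noise), spacing = 2)
  og <- opgdDetect(samp$response, list(npp = samp$npp, junk = samp$junk),
                   kRange = 4:6, nPerm = 49, seed = 8)
  ft <- factorTable(og)
  expect_identical(ft$factor[1], "npp")
  expect_gt(ft$q[1], ft$q[2])
  it <- interactionTable(og)
  expect_equal(nrow(it), 1L)
  expect_gte(it$q_ij, max(it$q_i, it$q_j) - 1e-12)
})
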