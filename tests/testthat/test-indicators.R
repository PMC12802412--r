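test_that("MNDWI and the water mask follow the band formula", {
  st <- makeStack(b1 = 0.1, b2 = 0.2,
                  b4 = matrix(c(0.3, 0.1, 0, 0.2), 2, 2),
                  b6 = matrix(c(0.1, 0.3, 0, 0.2), 2, 2), b7 = 0.1)
  m <- gridValues(computeMndwi(st))
  expect_equal(m[1, 1], 0.5)    # water
  expect_equal(m[2, 1], -0.5)   # land
  expect_true(is.na(m[1, 2]))   # 0/0 guard
  w <- waterMaskFromMndwi(computeMndwi(st), 0)
  expect_identical(as.vector(w), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("SAVI matches hand arithmetic and reduces to NDVI at L = 0", {
  st <- makeStack(b1 = 0.05, b2 = 0.3, b4 = 0.1, b6 = 0.2, b7 = 0.1)
  expect_equal(gridValues(computeSavi(st, L = 0.5))[1, 1],
               1.5 * 0.25 / 0.85, tolerance = 1e-9)
  expect_equal(gridValues(computeSavi(st, L = 0))[1, 1],
               (0.3 - 0.05) / (0.3 + 0.05), tolerance = 1e-12)
  stEq <- makeStack(b1 = 0.2, b2 = 0.2, b4 = 0.1, b6 = 0.2, b7 = 0.1)
  expect_equal(gridValues(computeSavi(stEq))[1, 1], 0)
})

test_that("SWCI and NDBBI follow their normalized-difference forms", {
  st <- makeStack(b1 = 0.1, b2 = 0.2, b4 = 0.1,
                  b6 = matrix(c(0.3, 0.1, 0.2, 0.4), 2, 2),
                  b7 = matrix(c(0.1, 0.3, 0.2, 0.1), 2, 2))
  sw <- gridValues(computeSwci(st))
  expect_equal(sw[1, 1], 0.5)
  expect_equal(sw[2, 1], -0.5)
  expect_equal(sw[1, 2], 0)

  st2 <- makeStack(b1 = 0.1, b2 = 0.2, b4 = 0.1, b6 = 0.4, b7 = 0.1)
  nd <- gridValues(computeNdbbi(st2))[1, 1]
  expect_equal(nd, (0.6 - 0.15) / (0.6 + 0.15), tolerance = 1e-9)
  # balanced numerator -> 0
  st3 <- makeStack(b1 = 0.1, b2 = 0.4, b4 = 0.2, b6 = 0.2, b7 = 0.1)
  expect_equal(gridValues(computeNdbbi(st3))[1, 1], 0)
  # alternative literal grouping differs
  alt <- gridValues(computeNdbbi(st2, grouping = "whole"))[1, 1]
  expect_equal(alt, (0.6 - 0.25) / (0.6 + 0.25), tolerance = 1e-12)
})

test_that("LST converts digital numbers to Celsius", {
  st <- makeStack(b1 = 0.1, b2 = 0.2, b4 = 0.1, b6 = 0.2, b7 = 0.1,
                  lstDn = matrix(c(14900, 13657.5, NA, 15000), 2, 2))
  lst <- gridValues(computeLst(st))
  expect_equal(lst[1, 1], 24.85, tolerance = 1e-9)
  expect_equal(lst[2, 1], 0, tolerance = 1e-9)
  expect_true(is.na(lst[1, 2]))
})

test_that("CSI reproduces the 3-pixel worked example", {
  st <- makeStack(b1 = matrix(c(0.1, 0.2, 0.3), 1, 3),
                  b2 = matrix(c(0.4, 0.3, 0.2), 1, 3),
                  b4 = matrix(0.1, 1, 3),
                  b6 = matrix(c(0.2, 0.3, 0.4), 1, 3),
                  b7 = matrix(0.1, 1, 3), nr = 1, nc = 3)
  csi <- as.vector(gridValues(computeCsi(st)))
  expect_equal(csi, c(0, 0.3888889, 1), tolerance = 1e-4)
  expect_error(computeCsi(makeStack(b1 = matrix(0.1, 1, 1),
                                    b2 = matrix(0.2, 1, 1),
                                    b4 = matrix(0.1, 1, 1),
                                    b6 = matrix(0.2, 1, 1),
                                    b7 = matrix(0.1, 1, 1), nr = 1, nc = 1)),
               "fewer than 2")
})

test_that("CSI equals the mean of its normalized sub-indices and stays in [0,1]", {
  st <- gradientStack(8, 8, seed = 3)
  b1 <- gridValues(stackBand(st, "b1")); b2 <- gridValues(stackBand(st, "b2"))
  b6 <- gridValues(stackBand(st, "b6"))
  nrm <- function(v) (v - min(v)) / (max(v) - min(v))
  expected <- (nrm(b1 / b2 * 100) + nrm((b1 - b2) / (b1 + b2)) +
               nrm(b6 / b2)) / 3
  got <- gridValues(computeCsi(st))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))
})

test_that("normalized-difference indices stay within [-1, 1] on valid bands", {
  set.seed(9)
  nr <- 6L; nc <- 6L
  st <- makeStack(b1 = matrix(runif(36, 0.01, 1), nr, nc),
                  b2 = matrix(runif(36, 0.01, 1), nr, nc),
                  b4 = matrix(runif(36, 0.01, 1), nr, nc),
                  b6 = matrix(runif(36, 0.01, 1), nr, nc),
                  b7 = matrix(runif(36, 0.01, 1), nr, nc),
                  nr = nr, nc = nc)
  for (f in list(computeSwci, computeMndwi)) {
    v <- gridValues(f(st))
    expect_true(all(abs(v[!is.na(v)]) <= 1))
  }
  v <- gridValues(computeNdbbi(st))
  expect_true(all(abs(v[!is.na(v)]) <= 1))
})

test_that("buildIndicatorSet masks water, normalizes layers, flags errors", {
  sim <- simulateScene(sceneSpec(shape = c(32, 32), seed = 21,
                                 waterFraction = 0.12, noiseSd = 0.004))
  ind <- buildIndicatorSet(sim$stack)
  expect_true(isNormalized(ind))
  expect_identical(waterMask(ind), sim$truth$waterMask)
  for (nm in indicatorNames(ind)) {
    v <- gridValues(indicatorLayer(ind, nm))
    expect_true(all(is.na(v[waterMask(ind)])), info = nm)
    land <- v[!is.na(v)]
    expect_equal(range(land), c(0, 1), tolerance = 1e-12, info = nm)
  }

  # scene without water: masks equal the band nodata union (here: none)
  simDry <- simulateScene(sceneSpec(shape = c(16, 16), seed = 4,
                                    waterFraction = 0))
  indDry <- buildIndicatorSet(simDry$stack)
  expect_false(any(waterMask(indDry)))
  expect_false(anyNA(gridValues(indicatorLayer(indDry, "savi"))))

  # all-water scene errors
  allWater <- makeStack(b1 = 0.05, b2 = 0.05, b4 = 0.30, b6 = 0.05,
                        b7 = 0.04, nr = 3, nc = 3)
  expect_error(buildIndicatorSet(allWater), "all-water")
})

test_that("implausible reflectance values are treated as nodata", {
  st <- makeStack(b1 = matrix(c(0.1, 2.5, 0.2, 0.3), 2, 2), b2 = 0.4,
                  b4 = 0.1, b6 = 0.2, b7 = 0.1)
  v <- gridValues(computeSavi(st))
  expect_true(is.na(v[2, 1]))
  expect_false(anyNA(v[-2]))
})
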