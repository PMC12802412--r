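test_that("change grading follows the five bins and printed examples", {
  t1 <- makeGrid(c(3, 2, 1, 2), 2, 2)
  t2 <- makeGrid(c(1, 2, 5, 1), 2, 2)
  cg <- changeGrade(t1, t2)
  d <- as.vector(gridValues(cg$deltaGrade))
  ty <- as.vector(gridValues(cg$changeType))
  expect_equal(d, c(-2, 0, 4, -1))
  expect_equal(changeTypeLabels()[ty],
               c("deteriorated significantly", "unchanged",
                 "improved significantly", "deteriorated"))
  expect_error(changeGrade(makeGrid(c(0, 2, 3, 4), 2, 2), t2), "1..5")
})

test_that("delta grades are antisymmetric and mass is conserved", {
  set.seed(31)
  for (rep in 1:20) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    v1 <- matrix(sample(1:5, nr * nc, TRUE), nr, nc)
    v2 <- matrix(sample(1:5, nr * nc, TRUE), nr, nc)
    v1[sample(nr * nc, nr)] <- NA
    a <- makeGrid(v1); b <- makeGrid(v2)
    dab <- gridValues(changeGrade(a, b)$deltaGrade)
    dba <- gridValues(changeGrade(b, a)$deltaGrade)
    expect_equal(dab, -dba)

    tab <- transitionMatrix(a, b)
    joint <- sum(!is.na(v1) & !is.na(v2))
    expect_equal(sum(tab$cells), joint)
    expect_equal(sum(tab$percent), 100, tolerance = 1e-9)
    # FROM marginals equal epoch-1 histogram on joint cells
    fromHist <- tapply(tab$cells, tab$from, sum)
    ref <- table(v1[!is.na(v1) & !is.na(v2)])
    expect_equal(as.vector(fromHist[names(ref)]), as.vector(unname(ref)))
    toHist <- tapply(tab$cells, tab$to, sum)
    refTo <- table(v2[!is.na(v1) & !is.na(v2)])
    expect_equal(as.vector(toHist[names(refTo)]), as.vector(unname(refTo)))
  }
})

test_that("transition table enumerates FROM-TO pairs with the diagonal", {
  t1 <- makeGrid(c(2, 3, 2, 5), 2, 2)
  t2 <- makeGrid(c(3, 3, 1, 5), 2, 2)
  tab <- transitionMatrix(t1, t2)
  expect_equal(nrow(tab), 4L)
  lookup <- function(f, t) tab$cells[tab$from == f & tab$to == t]
  expect_equal(lookup(2, 3), 1L)
  expect_equal(lookup(2, 1), 1L)
  expect_equal(lookup(3, 3), 1L)
  expect_equal(lookup(5, 5), 1L)

  same <- transitionMatrix(t1, t1)
  expect_true(all(same$from == same$to))
  expect_equal(sum(same$cells), 4L)
})

test_that("coefficient of variation matches hand values and the level bins", {
  mk <- function(...) lapply(list(...), function(v) makeGrid(v, 1, 1))
  cv <- coefficientOfVariation(mk(0.5, 0.5, 0.5))
  expect_equal(gridValues(cv$cv)[1, 1], 0)
  expect_equal(gridValues(cv$cvLevel)[1, 1], 1)

  cv <- coefficientOfVariation(mk(0.1, 0.3, 0.1, 0.3))
  expect_equal(gridValues(cv$cv)[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(gridValues(cv$cvLevel)[1, 1], 5)

  cv <- coefficientOfVariation(mk(1, 3, 1, 3), estimator = "mad")
  expect_equal(gridValues(cv$cv)[1, 1], 0.5, tolerance = 1e-12)

  expect_error(coefficientOfVariation(mk(1, 2)), "3 epochs")
  # nonpositive mean masked
  cv <- coefficientOfVariation(mk(-1, 0, 1))
  expect_true(is.na(gridValues(cv$cv)[1, 1]))
})

test_that("CV is scale invariant and its levels use the fixed breakpoints", {
  set.seed(7)
  x <- runif(12, 0.2, 0.9)
  grids <- lapply(x, function(v) makeGrid(v, 1, 1))
  grids2 <- lapply(x * 3, function(v) makeGrid(v, 1, 1))
  expect_equal(gridValues(coefficientOfVariation(grids)$cv),
               gridValues(coefficientOfVariation(grids2)$cv),
               tolerance = 1e-12)
  lv <- function(cv) pmin(findInterval(cv, c(0.1, 0.2, 0.3, 0.4)) + 1, 5)
  for (cvv in c(0.05, 0.15, 0.25, 0.35, 0.45, 0.7)) {
    # mean 1, population sd exactly cvv
    series <- lapply(1 + c(cvv, -cvv, cvv, -cvv),
                     function(v) makeGrid(v, 1, 1))
    got <- coefficientOfVariation(series)
    expect_equal(gridValues(got$cvLevel)[1, 1], lv(cvv), info = cvv)
  }
})

test_that("Hurst estimator behaves on white noise, ramps and alternations", {
  set.seed(42)
  h <- hurstRS(rnorm(1024))
  expect_gte(h, 0.45); expect_lte(h, 0.65)

  expect_gte(hurstRS(seq_len(64) / 64), 0.9)

  set.seed(1)
  hAlt <- hurstRS(rep(c(1, -1), 32) + rnorm(64, 0, 0.05))
  expect_lt(hAlt, 0.5)

  expect_true(is.na(hurstRS(rep(1, 16))))  # zero-variance segments skipped
  expect_true(is.na(hurstRS(rnorm(5))))    # too short
})

test_that("Hurst classes use the printed persistence bounds", {
  expect_equal(hurstClassLabels()[classifyHurst(c(0.30, 0.53, 0.65, 0.40,
                                                  0.50))],
               c("strong antisustainability", "weak sustainability",
                 "strong sustainability", "weak antisustainability",
                 "weak sustainability"))
})

test_that("Hurst map on a short epoch series is finite and classified", {
  sim <- simulateTimeseries(sceneSpec(shape = c(8, 8), seed = 19,
                                      waterFraction = 0, noiseSd = 0.01,
                                      epochs = 12))
  series <- lapply(sim$stacks, function(st) {
    rseiGrid(computeRsei(buildIndicatorSet(st)))
  })
  hu <- hurstExponent(series)
  h <- gridValues(hu$hurst)
  # the min-max anchor cells can be constant across epochs (zero-variance
  # series are masked, not estimated); everywhere else H is finite in (0, 1]
  expect_lte(mean(is.na(h)), 0.05)
  ok <- !is.na(h)
  expect_true(all(h[ok] > 0 & h[ok] <= 1))
  expect_true(all(gridValues(hu$hurstClass)[ok] %in% 1:4))
  expect_error(hurstExponent(series[1:5]), "8 epochs")
})
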