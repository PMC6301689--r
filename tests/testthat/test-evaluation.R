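# Agreement statistics and the phantom evaluation harness.

test_that("volume ratio is plain division with a guarded denominator", {
  expect_identical(volumeRatio(96.5, 96.5), 1)
  expect_equal(volumeRatio(213, 96.5), 2.207, tolerance = 1e-3)
  expect_identical(volumeRatio(0, 96.5), 0)
  expect_error(volumeRatio(10, 0), "positive")
})

test_that("median and range follow the sorting oracle", {
  expect_equal(medianRange(5), c(median = 5, min = 5, max = 5))
  expect_equal(medianRange(c(1, 2, 3, 4)), c(median = 2.5, min = 1, max = 4))
  expect_error(medianRange(numeric()), "non-empty")
  set.seed(4)
  for (i in 1:20) {
    x <- runif(sample(1:15, 1), -10, 300)
    s <- sort(x)
    n <- length(s)
    med <- if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    expect_equal(medianRange(x), c(median = med, min = s[1], max = s[n]))
  }
})

test_that("min-max scaling is anchored to the reference maximum", {
  x <- c(2, 5, 10)
  expect_equal(max(minmaxScaleVolumes(x)), 1)
  expect_identical(order(minmaxScaleVolumes(x)), order(x))
  expect_equal(minmaxScaleVolumes(2 * x, 2 * x), minmaxScaleVolumes(x, x))
  expect_equal(minmaxScaleVolumes(c(1, 2), c(4, 8)), c(0.125, 0.25))
  expect_error(minmaxScaleVolumes(c(1, 2), c(0, 0)), "positive")
})

test_that("Bland-Altman bias and limits behave under identity, shift and swap", {
  a <- c(1, 2, 3, 4.5)
  st <- blandAltman(a, a)
  expect_identical(c(st@bias, st@loaLow, st@loaHigh), c(0, 0, 0))
  sh <- blandAltman(a, a + 2)
  expect_equal(sh@bias, -2)
  expect_equal(sh@loaHigh - sh@loaLow, 0)
  set.seed(5)
  b <- a + rnorm(4)
  fwd <- blandAltman(a, b); rev <- blandAltman(b, a)
  expect_equal(fwd@bias, -rev@bias)
  expect_equal(fwd@loaLow, -rev@loaHigh)
  expect_equal(fwd@loaHigh, -rev@loaLow)
  # hand-computed oracle
  d <- a - b
  expect_equal(fwd@bias, mean(d))
  expect_equal(fwd@loaHigh, mean(d) + 1.96 * sd(d))
  expect_error(blandAltman(1, numeric()), "equal length")
  expect_error(blandAltman(1, 2), "two pairs")
})

test_that("ICC(2,1) matches the hand-computed mean-squares oracle", {
  # worked 6-pair table, ANOVA decomposition evaluated longhand
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  x <- cbind(a, b)
  n <- 6; k <- 2
  gm <- mean(x)
  msr <- k * sum((rowMeans(x) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - gm)^2) / (k - 1)
  mse <- (sum((x - gm)^2) - k * sum((rowMeans(x) - gm)^2) -
            n * sum((colMeans(x) - gm)^2)) / ((n - 1) * (k - 1))
  iccHand <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  st <- iccAgreement(a, b)
  expect_equal(st@icc, iccHand, tolerance = 1e-10)
  expect_lte(st@iccLow, st@icc)
  expect_gte(st@iccHigh, st@icc)
})

test_that("ICC is 1 for identical ratings and near 0 under independence", {
  a <- c(3, 1, 4, 1, 5, 9)
  st <- iccAgreement(a, a)
  expect_equal(st@icc, 1)
  set.seed(99)
  x <- rnorm(500); y <- rnorm(500)
  expect_lt(abs(iccAgreement(x, y)@icc), 0.15)
  expect_error(iccAgreement(rep(1, 6), rep(1, 6)), "variance")
})

test_that("the phantom experiment harness is deterministic and collapses at repeats = 1", {
  r1 <- runPhantomExperiment("ceora", repeats = 1, seed = 9L,
                             supersampling = 2L, noiseSigma = 0, jitterMM = 0)
  expect_equal(r1$perDensity$ccs_min, r1$perDensity$ccs_max)
  expect_equal(r1$perDensity$ccs_median, r1$perDensity$ccs_min)
  r2 <- runPhantomExperiment("ceora", repeats = 1, seed = 9L,
                             supersampling = 2L, noiseSigma = 0, jitterMM = 0)
  expect_identical(r1$perInsert, r2$perInsert)
  # density direction: higher HA density yields a larger C-CS/true ratio
  pd <- r1$perDensity
  ratios <- pd$ccs_median / pd$detected_true_mm3
  expect_gt(ratios[pd$density == 800], ratios[pd$density == 200])
})
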