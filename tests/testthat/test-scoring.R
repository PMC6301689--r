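# EM mixture fitting, the per-lesion threshold, fractional calcium
# content, and whole-scan scoring.

test_that("the per-lesion threshold follows the Gaussian FWHM closed form", {
  expect_identical(lesionThreshold(100, 0), 100)
  expect_equal(lesionThreshold(60, 15), 77.66, tolerance = 1e-4)
  expect_equal(lesionThreshold(0, 1), 1.17741, tolerance = 1e-5)
  expect_error(lesionThreshold(50, -1), "non-negative")
  # strictly increasing in both arguments
  set.seed(1)
  mu <- runif(20, -50, 200); s <- runif(20, 0, 60)
  expect_true(all(lesionThreshold(mu + 1, s) > lesionThreshold(mu, s)))
  expect_true(all(lesionThreshold(mu, s + 1) > lesionThreshold(mu, s)))
})

test_that("fractional calcium content scales linearly and clamps to [0, 1]", {
  expect_identical(partialContent(300, 100, 300), 1)
  expect_identical(partialContent(100, 100, 300), 0)
  expect_identical(partialContent(200, 100, 300), 0.5)
  # volume of a 3-voxel lesion with fractions 1 / 0.5 / 0 at 1 mm^3 voxels
  expect_equal(sum(partialContent(c(300, 200, 100), 100, 300)) * 1, 1.5)
  # single-intensity lesion: full calcium by convention
  expect_identical(partialContent(c(250, 250), 250, 250), c(1, 1))
  expect_error(partialContent(200, 300, 100), "xMax")
})

test_that("EM recovers well-separated mixture parameters", {
  set.seed(21)
  x <- c(rnorm(500, 60, 15), rnorm(500, 600, 100))
  fit <- fitTwoGaussianEM(x)
  expect_true(fit@converged)
  expect_false(fit@degenerate)
  expect_lt(abs(fit@muB / 60 - 1), 0.05)
  expect_lt(abs(fit@muF / 600 - 1), 0.05)
  expect_lt(abs(fit@sigmaB / 15 - 1), 0.15)
  expect_lt(abs(fit@sigmaF / 100 - 1), 0.15)
  expect_equal(sum(fit@weights), 1, tolerance = 1e-9)
  expect_gte(fit@muF, fit@muB)
})

test_that("EM flags degenerate and near-collapsed inputs", {
  # two distinct values: components land on them, SDs at the floor
  fit <- fitTwoGaussianEM(c(10, 500))
  expect_true(fit@degenerate)
  expect_equal(fit@muB, 10, tolerance = 1e-6)
  expect_equal(fit@muF, 500, tolerance = 1e-6)
  expect_equal(fit@sigmaB, 0.5)
  # identical values: no mixture
  expect_error(fitTwoGaussianEM(rep(100, 10)), "identical")
  # one Gaussian duplicated: means nearly coincide, flagged
  set.seed(3)
  y <- rnorm(400, 50, 15)
  fit2 <- fitTwoGaussianEM(c(y, y))
  expect_true(fit2@degenerate)
  expect_lt(abs(fit2@muF - fit2@muB), max(fit2@sigmaB, fit2@sigmaF))
})

test_that("clinical volume is voxel count times voxel volume", {
  hu <- array(0, c(5, 5, 3))
  hu[3, 3, 2] <- 500
  hu[2, 3, 2] <- 60                     # some background structure
  v <- CTVolume(hu, spacing = c(1, 1, 3))
  res <- scoreScan(v)
  s <- lesionScores(res)[[1]]
  expect_identical(s@nVoxels, 1L)
  expect_identical(s@ccsVolume, 3)
})

test_that("scored fractions are normalised with the peak voxel at 1", {
  set.seed(31)
  sim <- simulateAcquisition(phantomSpec(list(cylinderInsert(4, 4, 800)),
                                         supersampling = 4L, marginMM = 4,
                                         noiseSigma = 10, backgroundHU = 50))
  res <- scoreScan(sim$volume)
  for (s in lesionScores(res)) {
    expect_true(all(s@pvc >= 0 & s@pvc <= 1))
    expect_equal(max(s@pvc), 1)
    expect_gte(s@xMax, s@xMin)
    expect_gte(s@thresholdHU, s@em@muB)
  }
})

test_that("scan scoring is additive over disjoint lesions and deterministic", {
  hu <- array(10, c(12, 6, 2))
  hu[2:3, 3, 1] <- c(400, 300)
  hu[9:10, 3, 2] <- c(500, 250)
  v <- CTVolume(hu, spacing = c(1, 1, 3))
  res1 <- scoreScan(v)
  res2 <- scoreScan(v)
  expect_identical(res1@totals, res2@totals)
  expect_length(lesionScores(res1), 2L)
  perLesion <- vapply(lesionScores(res1), function(s) s@pvcVolume, 0)
  expect_equal(pvcTotal(res1), sum(perLesion))
  expect_equal(ccsTotal(res1), sum(vapply(lesionScores(res1),
                                          function(s) s@ccsVolume, 0)))
  expect_true(all(res1@status == "ok"))
})

test_that("corrected volume approaches truth where clinical scoring overestimates", {
  # high-density insert: C-CS inflated by partial volume, PVC-CS close
  sim <- simulateAcquisition(phantomSpec(list(cylinderInsert(5, 5, 800)),
                                         supersampling = 8L, noiseSigma = 0))
  res <- scoreScan(sim$volume)
  true <- cylinderVolume(5, 5)
  expect_gt(ccsTotal(res) / true, 1.3)
  expect_lt(abs(pvcTotal(res) / true - 1), 0.15)
})

test_that("per-lesion thresholds are independent across lesions", {
  hu <- array(0, c(16, 7, 2))
  hu[2:3, 4, 1] <- 1000                  # bright lesion on a 0 HU background
  hu[9:16, , ] <- 55                     # elevated plateau around the second
  hu[12:13, 4, 1] <- c(220, 180)
  v <- CTVolume(hu, spacing = c(1, 1, 3))
  res <- scoreScan(v)
  thr <- vapply(lesionScores(res), function(s) s@thresholdHU, 0)
  expect_length(thr, 2L)
  expect_false(isTRUE(all.equal(thr[1], thr[2])))
})

test_that("EM agrees with an independent mixture implementation", {
  library(mclust)
  set.seed(8)
  x <- c(rnorm(400, 40, 12), rnorm(300, 500, 80))
  ours <- fitTwoGaussianEM(x, tol = 1e-9)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  mus <- unname(sort(ref$parameters$mean))
  expect_equal(ours@muB, mus[1], tolerance = 0.02)
  expect_equal(ours@muF, mus[2], tolerance = 0.02)
})
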