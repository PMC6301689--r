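# Lesion detection, distance maps, extension and background definition.

mkVolume <- function(hu, spacing = c(1, 1, 3)) CTVolume(hu, spacing = spacing)

test_that("nothing above threshold gives an empty lesion list", {
  v <- mkVolume(array(runif(60, 0, 120), c(5, 4, 3)))
  expect_identical(detectLesions(v), list())
  res <- scoreScan(v)
  expect_identical(ccsTotal(res), 0)
  expect_identical(pvcTotal(res), 0)
})

test_that("corner-touching voxels join through 26-connectivity", {
  hu <- array(0, c(2, 2, 2))
  hu[1, 1, 1] <- 200
  hu[2, 2, 2] <- 200        # shares only a corner
  les <- detectLesions(mkVolume(hu))
  expect_length(les, 1L)
  expect_setequal(les[[1]], which(hu >= 130))
})

test_that("connected components match the brute-force oracle", {
  set.seed(42)
  for (i in 1:10) {
    dims <- sample(3:9, 3, replace = TRUE)
    m <- randomMaskGrid(dims, pTrue = runif(1, 0.2, 0.6))
    hu <- array(0, dims)
    hu[m] <- 200
    got <- componentsAsSets(detectLesions(mkVolume(hu)))
    want <- componentsAsSets(bfLabel26(m))
    expect_identical(got, want)
  }
})

test_that("anisotropic distance maps match exhaustive search", {
  # single voxel, spacing (1,1,3): nearest outside center is in-plane
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  expect_equal(anisotropicDistanceMap(m, c(1, 1, 3), "interior")[2, 2, 2], 1)
  # one slice step costs dz
  expect_equal(anisotropicDistanceMap(m, c(1, 1, 3), "exterior")[2, 2, 3], 3)
  # 3x3 in-plane square in a single 5x5 slice: center depth 2
  sq <- array(FALSE, c(5, 5, 1)); sq[2:4, 2:4, 1] <- TRUE
  expect_equal(anisotropicDistanceMap(sq, c(1, 1, 3), "interior")[3, 3, 1], 2)
  expect_error(anisotropicDistanceMap(array(FALSE, c(3, 3, 3)), c(1, 1, 3),
                                      "interior"), "empty")
  set.seed(7)
  for (i in 1:8) {
    dims <- sample(3:8, 3, replace = TRUE)
    sp <- sample(list(c(1, 1, 3), c(0.4, 0.4, 3), c(1, 2, 3)), 1)[[1]]
    m <- randomMaskGrid(dims, 0.4)
    if (!any(m) || all(m)) next
    ext <- anisotropicDistanceMap(m, sp, "exterior")
    bf <- bfDistanceToMask(m, sp)
    expect_equal(ext[!m], bf[!m], tolerance = 1e-10)
    int <- anisotropicDistanceMap(m, sp, "interior")
    bfI <- bfDistanceToMask(!m, sp)
    expect_equal(int[m], bfI[m], tolerance = 1e-10)
  }
})

test_that("lesion extension keeps only >90 HU voxels within d1 of the initial mask", {
  # single-voxel lesion: d1 = 1 (in-plane). A 100 HU face neighbor stays;
  # a second 100 HU voxel connected through it (distance 2) is discarded.
  hu <- array(0, c(5, 5, 1))
  hu[2, 3, 1] <- 200
  hu[3, 3, 1] <- 100
  hu[4, 3, 1] <- 100
  v <- mkVolume(hu)
  init <- detectLesions(v)[[1]]
  ext <- extendLesion(v, init)
  expect_equal(ext$d1, 1)
  expect_identical(ext$extendedIdx, 13L)   # linear index of (3, 3, 1)
  # nothing between 90 and 130 adjacent -> empty extension
  hu2 <- array(0, c(4, 4, 1)); hu2[2, 2, 1] <- 300
  ext2 <- extendLesion(mkVolume(hu2), detectLesions(mkVolume(hu2))[[1]])
  expect_length(ext2$extendedIdx, 0L)
  # exactly 90 HU is not "above 90": excluded
  hu3 <- array(0, c(4, 4, 1)); hu3[2, 2, 1] <- 300; hu3[3, 2, 1] <- 90
  ext3 <- extendLesion(mkVolume(hu3), detectLesions(mkVolume(hu3))[[1]])
  expect_length(ext3$extendedIdx, 0L)
})

test_that("the background shell is the d2 neighborhood minus other lesions", {
  # isotropic single voxel: d2 = 1, background = the 6 face neighbors
  hu <- array(0, c(5, 5, 5))
  hu[3, 3, 3] <- 500
  v <- CTVolume(hu, spacing = c(1, 1, 1))
  calc <- detectLesions(v)[[1]]
  bg <- defineBackground(v, calc)
  expect_equal(bg$d2, 1)
  nb <- arrayInd(bg$backgroundIdx, dim(hu))
  expect_identical(nrow(nb), 6L)
  expect_true(all(rowSums(abs(sweep(nb, 2, c(3, 3, 3)))) == 1))
  # border lesion: clipped, no out-of-bounds indices
  hu2 <- array(0, c(3, 3, 2)); hu2[1, 1, 1] <- 500
  v2 <- mkVolume(hu2)
  bg2 <- defineBackground(v2, detectLesions(v2)[[1]])
  expect_true(all(bg2$backgroundIdx >= 1 & bg2$backgroundIdx <= length(hu2)))
  # two nearby lesions: neither background contains the other's calcium
  hu3 <- array(0, c(9, 5, 1))
  hu3[2:3, 3, 1] <- 400
  hu3[6:7, 3, 1] <- 400
  v3 <- mkVolume(hu3)
  segs <- segmentLesions(v3)
  expect_length(segs, 2L)
  expect_length(intersect(backgroundIndices(segs[[1]]),
                          calcificationIndices(segs[[2]])), 0L)
  expect_length(intersect(backgroundIndices(segs[[2]]),
                          calcificationIndices(segs[[1]])), 0L)
})

test_that("segmentation masks nest and stay in bounds", {
  set.seed(11)
  sim <- simulateAcquisition(phantomSpec(list(cylinderInsert(4, 4, 400)),
                                         supersampling = 4L, marginMM = 4,
                                         noiseSigma = 10))
  segs <- segmentLesions(sim$volume)
  expect_gte(length(segs), 1L)
  for (sg in segs) {
    expect_true(all(initialIndices(sg) %in% calcificationIndices(sg)))
    expect_length(intersect(initialIndices(sg), extendedIndices(sg)), 0L)
    expect_length(intersect(backgroundIndices(sg), calcificationIndices(sg)), 0L)
    n <- prod(dim(sim$volume))
    idx <- c(calcificationIndices(sg), backgroundIndices(sg))
    expect_true(all(idx >= 1 & idx <= n))
    # extension shell: blurred cylinder grows beyond the initial mask
    expect_gte(length(calcificationIndices(sg)), length(initialIndices(sg)))
  }
})

test_that("raising the detection threshold never grows the initial masks", {
  set.seed(13)
  hu <- array(runif(400, 0, 400), c(10, 10, 4))
  v <- mkVolume(hu)
  counts <- sapply(c(90, 130, 200, 300), function(th)
    sum(lengths(detectLesions(v, detectionHU = th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("each ground-truth insert maps to exactly one lesion on a clean phantom", {
  sim <- simulateAcquisition(phantomSpec(
    list(cylinderInsert(5, 5, 800, c(-8, 0, 0)),
         cylinderInsert(3, 3, 400, c(8, 0, 0))),
    supersampling = 4L, marginMM = 4, noiseSigma = 0))
  segs <- segmentLesions(sim$volume)
  expect_length(segs, 2L)
  hits <- sapply(sim$truth@occupancy, function(occ)
    sum(sapply(segs, function(sg) sum(occ[initialIndices(sg)]) > 0)))
  expect_true(all(hits == 1))
})
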