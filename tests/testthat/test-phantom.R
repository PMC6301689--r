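# Phantom simulator: rasterisation accuracy, intensity conservation,
# determinism, motion behaviour, and the replica presets.

fastSpec <- function(inserts, ...) {
  phantomSpec(inserts, supersampling = 4L, marginMM = 4, ...)
}

test_that("an insert-free spec yields a uniform background volume", {
  sim <- simulateAcquisition(phantomSpec(list(), backgroundHU = 50,
                                         supersampling = 2L, noiseSigma = 0))
  expect_true(all(intensities(sim$volume) == 50))
  expect_identical(nrow(sim$truth@volumes), 0L)
})

test_that("blur and block-averaging conserve integrated excess intensity", {
  ins <- list(cylinderInsert(5, 5, 800))
  vols <- sapply(c(0.3, 0.6, 1.2), function(ps) {
    sim <- simulateAcquisition(fastSpec(ins, noiseSigma = 0, psfSigma = ps))
    v <- sim$volume
    sum(intensities(v)) * voxelVolume(v) / haToHU(800)
  })
  true <- cylinderVolume(5, 5)
  expect_true(all(abs(vols / true - 1) < 0.01))
  expect_lt(max(abs(vols - vols[1])) / vols[1], 0.005)   # PSF-invariant
  # motion blur (unit-sum box kernel) conserves the integral too
  simM <- simulateAcquisition(fastSpec(ins, noiseSigma = 0, motionVelocity = 10))
  vM <- sum(intensities(simM$volume)) * voxelVolume(simM$volume) / haToHU(800)
  expect_lt(abs(vM / true - 1), 0.01)
})

test_that("fractional-occupancy ground truth matches analytic volumes", {
  # the supersampling contract: <= 1% relative error at factor 8
  specs <- list(cylinderInsert(5, 5, 800), cylinderInsert(1, 1, 200),
                segmentInsert(2, 0.5, 10, 400, theta = 60))
  for (ins in specs) {
    sim <- simulateAcquisition(phantomSpec(list(ins), supersampling = 8L,
                                           marginMM = 4, noiseSigma = 0))
    gt <- sum(sim$truth@occupancy[[1]]) * voxelVolume(sim$volume)
    expect_lt(abs(gt / trueVolume(ins) - 1), 0.01)
  }
})

test_that("identical specs give bit-identical volumes; noise is the only seed effect", {
  spec <- fastSpec(list(cylinderInsert(3, 3, 400)), noiseSigma = 12, seed = 5L)
  a <- simulateAcquisition(spec)
  b <- simulateAcquisition(spec)
  expect_identical(intensities(a$volume), intensities(b$volume))
  spec2 <- fastSpec(list(cylinderInsert(3, 3, 400)), noiseSigma = 12, seed = 6L)
  c2 <- simulateAcquisition(spec2)
  expect_false(identical(intensities(a$volume), intensities(c2$volume)))
  # no jitter: geometry (ground truth) unchanged across seeds
  expect_equal(a$truth@occupancy, c2$truth@occupancy)
  expect_identical(a$truth@volumes, c2$truth@volumes)
})

test_that("peak intensity is non-increasing in motion velocity", {
  peaks <- sapply(c(0, 10, 30), function(v) {
    sim <- simulateAcquisition(fastSpec(list(segmentInsert(2, 2, 10, 800)),
                                        noiseSigma = 0, motionVelocity = v,
                                        backgroundHU = 50))
    max(intensities(sim$volume))
  })
  expect_true(all(diff(peaks) <= 1e-9))
})

test_that("replica presets encode the documented phantom layouts", {
  ce <- makeCeoraSpec("none")
  expect_length(ce@inserts, 9L)
  vols <- vapply(ce@inserts, trueVolume, 0)
  dens <- vapply(ce@inserts, function(i) i@density, 0)
  for (d in c(800, 400, 200))
    expect_equal(round(sum(vols[dens == d]), 1), 98.2 + 21.2 + 0.8)
  sa <- makeSatiSpec(0)
  expect_length(sa@inserts, 9L)
  expect_equal(sa@backgroundHU, 50)
  expect_setequal(round(vapply(sa@inserts, trueVolume, 0), 1),
                  c(62.8, 24.6, 9.1))
  expect_equal(makeSatiSpec(30)@motionVelocity, 30)
  # larger girth ring -> more noise, by construction
  expect_lt(makeCeoraSpec("none")@noiseSigma, makeCeoraSpec("M")@noiseSigma)
  expect_lt(makeCeoraSpec("M")@noiseSigma, makeCeoraSpec("L")@noiseSigma)
  expect_error(makeSatiSpec(-1), "non-negative")
})

test_that("the supersampled-grid memory budget is enforced", {
  expect_error(simulateAcquisition(phantomSpec(list(cylinderInsert(5, 5, 800)),
                                               maxVoxels = 1e4)),
               "maxVoxels")
})

test_that("paired reconstructions share one acquisition", {
  spec <- fastSpec(list(cylinderInsert(4, 4, 400)), backgroundHU = 50, seed = 3L)
  pair <- simulatePairedReconstructions(spec)
  expect_identical(dim(pair$sharp), dim(pair$soft))
  # sharp kernel preserves a higher peak than soft
  expect_gt(max(intensities(pair$sharp)), max(intensities(pair$soft)))
  # same ground truth object
  expect_equal(sum(pair$truth@occupancy[[1]]) * voxelVolume(pair$sharp),
               trueVolume(spec@inserts[[1]]), tolerance = 0.01)
})
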