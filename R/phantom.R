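## Digital phantom simulation. The pipeline is image-domain: analytic
## rasterisation on a supersampled grid, optional transverse motion box
## blur, in-plane Gaussian PSF, block-averaging down to the reconstruction
## grid (this is where the partial volume effect arises), then additive
## Gaussian noise on the reconstruction grid. No projection-domain physics.

## Grid layout for one acquisition. Reconstruction voxel centers are at
## origin + (i-1)*spacing; the supersampled grid subdivides each in-plane
## voxel by `f` and uses a z step of sliceThickness/f so that each slice is
## the mean over a window of supersampled planes (windows overlap when the
## increment is below the thickness).
.phantomGrid <- function(spec) {
  f <- spec@supersampling
  dx <- spec@inPlaneSpacing
  th <- spec@sliceThickness
  inc <- spec@sliceIncrement
  if (length(spec@inserts)) {
    bb <- sapply(spec@inserts, function(ins) {
      r <- if (ins@shape == "cylinder") ins@diameter / 2 else ins@radius
      c(ins@center[1] - r, ins@center[1] + r,
        ins@center[2] - r, ins@center[2] + r,
        ins@center[3] - ins@length / 2, ins@center[3] + ins@length / 2)
    })
    lim <- c(min(bb[1, ]), max(bb[2, ]), min(bb[3, ]), max(bb[4, ]),
             min(bb[5, ]), max(bb[6, ]))
  } else lim <- c(-5, 5, -5, 5, -5, 5)
  mblur <- spec@motionVelocity * spec@exposureTime / 2
  mx <- spec@marginMM + 3 * spec@psfSigma + mblur + spec@jitterMM[1]
  my <- spec@marginMM + 3 * spec@psfSigma + spec@jitterMM[2]
  mz <- spec@marginMM + spec@jitterMM[3]

  nx <- ceiling((lim[2] - lim[1] + 2 * mx) / dx)
  ny <- ceiling((lim[4] - lim[3] + 2 * my) / dx)
  nz <- max(1L, ceiling((lim[6] - lim[5] + 2 * mz - th) / inc) + 1L)
  xc <- (lim[1] + lim[2]) / 2
  yc <- (lim[3] + lim[4]) / 2
  zc <- (lim[5] + lim[6]) / 2
  originX <- xc - (nx - 1) / 2 * dx
  originY <- yc - (ny - 1) / 2 * dx
  sliceCenters <- zc - (nz - 1) / 2 * inc + (seq_len(nz) - 1) * inc

  dss <- dx / f
  dzss <- th / f
  zlo <- sliceCenters[1] - th / 2
  zhi <- sliceCenters[nz] + th / 2
  nzss <- max(1L, round((zhi - zlo) / dzss))
  ssx <- originX - dx / 2 + dss / 2 + (seq_len(nx * f) - 1) * dss
  ssy <- originY - dx / 2 + dss / 2 + (seq_len(ny * f) - 1) * dss
  ssz <- zlo + dzss / 2 + (seq_len(nzss) - 1) * dzss
  if (as.double(nx) * f * ny * f * nzss > spec@maxVoxels)
    stop(sprintf("supersampled grid (%g voxels) exceeds maxVoxels budget (%g)",
                 as.double(nx) * f * ny * f * nzss, spec@maxVoxels))
  zwin <- lapply(sliceCenters, function(ck)
    which(ssz >= ck - th / 2 - 1e-9 & ssz < ck + th / 2 - 1e-9))

  list(f = f, reconDim = c(nx, ny, nz),
       reconSpacing = c(dx, dx, inc),
       reconOrigin = c(originX, originY, sliceCenters[1]),
       ssDim = c(nx * f, ny * f, nzss), ssSpacing = c(dss, dss, dzss),
       ssx = ssx, ssy = ssy, ssz = ssz, zwin = zwin)
}

## Fractional occupancy of one insert on a supersampled sub-block.
## In-plane: 3x3 sub-voxel sampling of the cross-section indicator;
## z: exact interval overlap of the voxel extent with the insert length.
## Returns NULL when the insert misses the grid, else a list with the
## index ranges and the fraction array.
.rasterInsert <- function(ins, grid, shift = c(0, 0, 0)) {
  ctr <- ins@center + shift
  r <- if (ins@shape == "cylinder") ins@diameter / 2 else ins@radius
  ix <- which(grid$ssx >= ctr[1] - r - grid$ssSpacing[1] &
              grid$ssx <= ctr[1] + r + grid$ssSpacing[1])
  iy <- which(grid$ssy >= ctr[2] - r - grid$ssSpacing[2] &
              grid$ssy <= ctr[2] + r + grid$ssSpacing[2])
  z0 <- ctr[3] - ins@length / 2
  z1 <- ctr[3] + ins@length / 2
  dz <- grid$ssSpacing[3]
  zf <- pmax(0, (pmin(grid$ssz + dz / 2, z1) - pmax(grid$ssz - dz / 2, z0)) / dz)
  iz <- which(zf > 0)
  if (!length(ix) || !length(iy) || !length(iz)) return(NULL)

  xs <- grid$ssx[ix] - ctr[1]
  ys <- grid$ssy[iy] - ctr[2]
  off <- c(-1, 0, 1) * grid$ssSpacing[1] / 3
  frac2d <- matrix(0, length(xs), length(ys))
  for (ox in off) for (oy in off) {
    X <- matrix(xs + ox, length(xs), length(ys))
    Y <- matrix(ys + oy, length(xs), length(ys), byrow = TRUE)
    if (ins@shape == "cylinder") {
      inside <- X^2 + Y^2 <= r^2
    } else {
      a <- ins@theta * pi / 180
      U <- X * cos(a) + Y * sin(a)
      V <- -X * sin(a) + Y * cos(a)
      inside <- (U^2 + V^2 <= r^2) & (V >= r - ins@capHeight)
    }
    frac2d <- frac2d + inside
  }
  frac2d <- frac2d / 9
  frac <- outer(frac2d, zf[iz])
  list(ix = ix, iy = iy, iz = iz, frac = frac)
}

.gaussKernel <- function(sigmaVox) {
  r <- max(1L, ceiling(3.5 * sigmaVox))
  k <- dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

.boxKernel <- function(widthVox) {
  n <- max(1L, round(widthVox))
  if (n %% 2L == 0L) n <- n + 1L
  rep(1 / n, n)
}

## In-plane f x f block mean followed by z window means.
.downsample <- function(a, grid) {
  f <- grid$f
  d <- grid$ssDim
  nx <- d[1] %/% f; ny <- d[2] %/% f
  a <- colMeans(array(a, c(f, nx, d[2] * d[3])))       # collapse x blocks
  a <- array(a, c(nx, f, ny, d[3]))
  a <- colMeans(aperm(a, c(2, 1, 3, 4)))               # collapse y blocks
  nz <- grid$reconDim[3]
  out <- array(0, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    j <- grid$zwin[[k]]
    out[, , k] <- rowMeans(a[, , j, drop = FALSE], dims = 2)
  }
  out
}

## Fractional occupancy of one rasterised insert block on the
## reconstruction grid, without touching the full supersampled array:
## the block is zero-padded to f-aligned in-plane ranges, block-averaged,
## and its z planes are averaged into the slice windows they fall in.
.blockToRecon <- function(blk, grid) {
  f <- grid$f
  ix0 <- ((min(blk$ix) - 1L) %/% f) * f + 1L
  ix1 <- ((max(blk$ix) - 1L) %/% f) * f + f
  iy0 <- ((min(blk$iy) - 1L) %/% f) * f + 1L
  iy1 <- ((max(blk$iy) - 1L) %/% f) * f + f
  nzb <- length(blk$iz)
  Fa <- array(0, c(ix1 - ix0 + 1L, iy1 - iy0 + 1L, nzb))
  Fa[blk$ix - ix0 + 1L, blk$iy - iy0 + 1L, ] <- blk$frac
  nxb <- (ix1 - ix0 + 1L) %/% f
  nyb <- (iy1 - iy0 + 1L) %/% f
  a <- colMeans(array(Fa, c(f, nxb, (iy1 - iy0 + 1L) * nzb)))
  a <- array(a, c(nxb, f, nyb, nzb))
  a <- colMeans(aperm(a, c(2, 1, 3, 4)))
  occ <- array(0, grid$reconDim)
  rx <- ((ix0 - 1L) %/% f + 1L):((ix1 - 1L) %/% f + 1L)
  ry <- ((iy0 - 1L) %/% f + 1L):((iy1 - 1L) %/% f + 1L)
  for (k in seq_len(grid$reconDim[3])) {
    jz <- which(blk$iz %in% grid$zwin[[k]])
    if (!length(jz)) next
    occ[rx, ry, k] <- occ[rx, ry, k] +
      rowSums(a[, , jz, drop = FALSE], dims = 2) / length(grid$zwin[[k]])
  }
  occ
}

#' Rasterise a phantom onto the supersampled acquisition grid
#'
#' Produces the noiseless, PSF-free "master" of one acquisition: the
#' supersampled HU field with the random repositioning jitter and the
#' transverse motion blur already applied, plus the ground truth at the
#' reconstruction grid. Jitter is drawn from the current RNG state, so
#' call [set.seed()] (or use [simulateAcquisition()], which seeds from the
#' spec) beforehand.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements \code{huSS} (supersampled HU array),
#'   \code{grid} (grid geometry), \code{truth} (a [GroundTruth-class]),
#'   and \code{spec}.
#' @seealso [reconstructVolume()], [simulateAcquisition()]
#' @export
rasterizePhantom <- function(spec) {
  grid <- .phantomGrid(spec)
  shift <- if (any(spec@jitterMM > 0))
    runif(3, -spec@jitterMM, spec@jitterMM) else c(0, 0, 0)

  huSS <- array(spec@backgroundHU, grid$ssDim)
  occRecon <- vector("list", length(spec@inserts))
  for (j in seq_along(spec@inserts)) {
    ins <- spec@inserts[[j]]
    blk <- .rasterInsert(ins, grid, shift)
    if (is.null(blk)) {
      occRecon[[j]] <- array(0, grid$reconDim)
      next
    }
    huIns <- haToHU(ins@density, spec@calibration)
    huSS[blk$ix, blk$iy, blk$iz] <-
      huSS[blk$ix, blk$iy, blk$iz] + blk$frac * (huIns - spec@backgroundHU)
    occRecon[[j]] <- .blockToRecon(blk, grid)
  }

  if (spec@motionVelocity > 0) {
    w <- spec@motionVelocity * spec@exposureTime / grid$ssSpacing[1]
    if (w > 1)
      huSS <- array(.convolveAxis(huSS, grid$ssDim, .boxKernel(w), 1L),
                    grid$ssDim)
  }

  vols <- data.frame(
    insert_id = seq_along(spec@inserts),
    shape = vapply(spec@inserts, function(i) i@shape, ""),
    density = vapply(spec@inserts, function(i) i@density, 0),
    true_volume_mm3 = vapply(spec@inserts, trueVolume, 0))
  truth <- new("GroundTruth", volumes = vols, occupancy = occRecon)
  list(huSS = huSS, grid = grid, truth = truth, spec = spec)
}

#' Reconstruct a CT volume from a rasterised acquisition
#'
#' Applies the in-plane Gaussian PSF of the reconstruction kernel to the
#' supersampled master, block-averages to the reconstruction grid and adds
#' i.i.d. Gaussian noise (drawn from the current RNG state). Running this
#' twice on one master with different PSF/noise settings emulates paired
#' sharp/soft reconstructions of a single acquisition.
#'
#' @param master output of [rasterizePhantom()].
#' @param psfSigma in-plane PSF sigma, mm.
#' @param noiseSigma additive noise SD, HU.
#' @return A [CTVolume-class].
#' @export
reconstructVolume <- function(master, psfSigma, noiseSigma) {
  grid <- master$grid
  hu <- master$huSS
  if (psfSigma > 0) {
    k <- .gaussKernel(psfSigma / grid$ssSpacing[1])
    hu <- .convolveAxis(hu, grid$ssDim, k, 1L)
    hu <- .convolveAxis(hu, grid$ssDim, k, 2L)
  }
  hu <- array(hu, grid$ssDim)
  rec <- .downsample(hu, grid)
  if (noiseSigma > 0)
    rec <- rec + array(rnorm(length(rec), 0, noiseSigma), dim(rec))
  CTVolume(rec, spacing = grid$reconSpacing, origin = grid$reconOrigin)
}

#' Simulate one phantom CT acquisition
#'
#' Runs the full image-domain pipeline of [rasterizePhantom()] and
#' [reconstructVolume()] with every source of randomness (repositioning
#' jitter, noise) seeded from \code{spec@seed}, so identical specs give
#' bit-identical volumes.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with \code{volume} (a [CTVolume-class]) and
#'   \code{truth} (a [GroundTruth-class]).
#' @examples
#' spec <- phantomSpec(list(cylinderInsert(5, 5, 800)), supersampling = 4L)
#' sim <- simulateAcquisition(spec)
#' sim$volume
#' @export
simulateAcquisition <- function(spec) {
  set.seed(spec@seed)
  master <- rasterizePhantom(spec)
  vol <- reconstructVolume(master, spec@psfSigma, spec@noiseSigma)
  list(volume = vol, truth = master$truth)
}

#' Simulate paired sharp/soft reconstructions of one acquisition
#'
#' One noiseless master raster is reconstructed twice: a "sharp" kernel
#' surrogate (smaller PSF sigma, more noise) and a "soft" one (larger PSF
#' sigma, less noise). The pair shares the acquisition geometry exactly,
#' mirroring two reconstructions of one scan; the noise realisations are
#' independent.
#'
#' @param spec a [PhantomSpec-class] (its own psf/noise settings are
#'   ignored here).
#' @param sharp,soft named numeric vectors c(psf = , noise = ) in mm / HU.
#' @return list(sharp =, soft = [CTVolume-class], truth =
#'   [GroundTruth-class]).
#' @export
simulatePairedReconstructions <- function(spec,
                                          sharp = c(psf = 0.4, noise = 18),
                                          soft = c(psf = 0.8, noise = 8)) {
  set.seed(spec@seed)
  master <- rasterizePhantom(spec)
  vSharp <- reconstructVolume(master, sharp[["psf"]], sharp[["noise"]])
  vSoft <- reconstructVolume(master, soft[["psf"]], soft[["noise"]])
  list(sharp = vSharp, soft = vSoft, truth = master$truth)
}

#' Replica phantom specifications
#'
#' \code{makeCeoraSpec()} builds the cylindrical-insert calcium phantom:
#' nine cylinders, three sizes (98.2, 21.2, 0.8 mm^3) times three HA
#' densities (800, 400, 200 mg/cm^3), arranged in the transverse plane and
#' oriented along z, scanned at 3/3 mm slices. Extension rings emulating
#' patient girth enter as increased noise (none/M/L = 10/15/20 HU).
#' \code{makeSatiSpec()} builds the moving-artery phantom: three artificial
#' arteries in a 50 HU blood-equivalent background, each holding
#' circular-segment inserts of 62.8, 24.6 and 9.1 mm^3 mutually rotated by
#' +/-60 degrees, with optional transverse motion at 10 or 30 mm/s.
#' Both replicas reposition the phantom by a random sub-voxel translation
#' between acquisitions (seeded).
#'
#' @param ring extension ring: "none", "M" or "L".
#' @param velocity transverse motion speed in mm/s (0, 10 or 30 in the
#'   replica protocol; any non-negative value is accepted).
#' @param seed RNG seed of the acquisition.
#' @param supersampling rasterisation factor.
#' @param noiseSigma noise SD in HU; NULL uses the replica default (the
#'   ring-dependent 10/15/20 HU for the cylinder phantom, 10 HU for the
#'   moving-artery phantom).
#' @param jitterMM per-axis repositioning half-width, mm.
#' @param ... further arguments passed to [phantomSpec()].
#' @return A [PhantomSpec-class].
#' @examples
#' makeCeoraSpec("M", seed = 7)
#' makeSatiSpec(30, seed = 7)
#' @export
makeCeoraSpec <- function(ring = c("none", "M", "L"), seed = 1L,
                          supersampling = 8L, noiseSigma = NULL,
                          jitterMM = c(0.2, 0.2, 1.5), ...) {
  ring <- match.arg(ring)
  noise <- if (is.null(noiseSigma)) c(none = 10, M = 15, L = 20)[[ring]]
           else noiseSigma
  sizes <- list(c(5, 5), c(3, 3), c(1, 1))       # (diameter, length) mm
  dens <- c(800, 400, 200)
  inserts <- list()
  for (i in seq_along(sizes))
    for (j in seq_along(dens))
      inserts[[length(inserts) + 1L]] <- cylinderInsert(
        sizes[[i]][1], sizes[[i]][2], dens[j],
        center = c((j - 2) * 12, (i - 2) * 12, 0))
  phantomSpec(inserts, backgroundHU = 0, noiseSigma = noise,
              jitterMM = jitterMM, seed = seed,
              supersampling = supersampling, ...)
}

#' @rdname makeCeoraSpec
#' @export
makeSatiSpec <- function(velocity = 0, seed = 1L, supersampling = 8L,
                         noiseSigma = 10, jitterMM = c(0.2, 0.2, 1.5), ...) {
  if (velocity < 0) stop("velocity must be non-negative")
  dens <- c(800, 400, 200)
  caps <- c(2, 1, 0.5)                            # cap heights, mm
  thetas <- c(0, 60, -60)
  inserts <- list()
  for (j in seq_along(dens))                      # one artery per density
    for (i in seq_along(caps))
      inserts[[length(inserts) + 1L]] <- segmentInsert(
        radius = 2, capHeight = caps[i], length = 10, density = dens[j],
        center = c((j - 2) * 10, 0, (i - 2) * 18), theta = thetas[i])
  phantomSpec(inserts, backgroundHU = 50, noiseSigma = noiseSigma,
              motionVelocity = velocity, jitterMM = jitterMM,
              seed = seed, supersampling = supersampling, ...)
}
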