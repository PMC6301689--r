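## Central S4 containers. All geometry is voxel-center based: world
## coordinate = origin + (index - 1) * spacing, indices 1-based, axis order
## (x, y, z) with z the slice direction.

#' CTVolume: a 3D CT intensity grid in Hounsfield units
#'
#' @slot intensities 3D numeric array of HU values, axis order (x, y, z).
#' @slot spacing numeric(3), voxel spacing in mm; dz may exceed dx, dy.
#' @slot origin numeric(3), world position (mm) of the center of voxel
#'   (1,1,1).
#' @export
setClass("CTVolume",
  representation(intensities = "array", spacing = "numeric", origin = "numeric"),
  prototype(intensities = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values")
  if (any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a CTVolume
#'
#' @param intensities 3D array of HU values (x, y, z order).
#' @param spacing voxel spacing in mm, length 3.
#' @param origin world coordinate (mm) of the first voxel center.
#' @return A [CTVolume-class] object.
#' @examples
#' v <- CTVolume(array(0, c(4, 4, 2)), spacing = c(0.4, 0.4, 3))
#' voxelVolume(v)
#' @export
CTVolume <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("CTVolume", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' InsertSpec: one calcification insert of a digital phantom
#'
#' Cylinders are described by diameter and length; circular segments (a
#' cylinder cut by a plane parallel to its axis, "half cylindrical shape")
#' by radius, cap height and length. Both are extruded along z, the CT
#' scanning direction.
#'
#' @slot shape "cylinder" or "circular_segment".
#' @slot diameter cylinder diameter in mm (NA for segments).
#' @slot radius segment radius in mm (NA for cylinders).
#' @slot capHeight segment cap height in mm, 0 <= h <= 2r (NA for cylinders).
#' @slot length extent along z in mm.
#' @slot density hydroxyapatite density in mg/cm^3.
#' @slot center numeric(3) world position of the insert center in mm.
#' @slot theta in-plane rotation of the segment's cap axis in degrees.
#' @export
setClass("InsertSpec",
  representation(shape = "character", diameter = "numeric", radius = "numeric",
                 capHeight = "numeric", length = "numeric", density = "numeric",
                 center = "numeric", theta = "numeric"))

setValidity("InsertSpec", function(object) {
  msg <- character()
  if (!object@shape %in% c("cylinder", "circular_segment"))
    msg <- c(msg, "shape must be 'cylinder' or 'circular_segment'")
  if (object@length <= 0) msg <- c(msg, "length must be strictly positive")
  if (object@density < 0) msg <- c(msg, "density must be non-negative")
  if (length(object@center) != 3L) msg <- c(msg, "center must have length 3")
  if (object@shape == "cylinder") {
    if (!isTRUE(object@diameter > 0))
      msg <- c(msg, "cylinder diameter must be strictly positive")
  } else {
    if (!isTRUE(object@radius > 0))
      msg <- c(msg, "segment radius must be strictly positive")
    if (!isTRUE(object@capHeight > 0) ||
        isTRUE(object@capHeight > 2 * object@radius + 1e-12))
      msg <- c(msg, "cap height must satisfy 0 < h <= 2 * radius")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname InsertSpec-class
#' @param diameter,radius,capHeight,length insert dimensions in mm.
#' @param density hydroxyapatite density in mg/cm^3.
#' @param center insert center in world mm.
#' @param theta segment cap orientation in degrees (about z).
#' @export
cylinderInsert <- function(diameter, length, density, center = c(0, 0, 0)) {
  new("InsertSpec", shape = "cylinder", diameter = diameter, radius = NA_real_,
      capHeight = NA_real_, length = length, density = density,
      center = as.numeric(center), theta = 0)
}

#' @rdname InsertSpec-class
#' @export
segmentInsert <- function(radius, capHeight, length, density,
                          center = c(0, 0, 0), theta = 0) {
  new("InsertSpec", shape = "circular_segment", diameter = NA_real_,
      radius = radius, capHeight = capHeight, length = length,
      density = density, center = as.numeric(center), theta = theta)
}

#' PhantomSpec: a declarative virtual phantom acquisition
#'
#' @slot inserts list of [InsertSpec-class] objects.
#' @slot backgroundHU HU of the surrounding medium.
#' @slot inPlaneSpacing reconstructed in-plane voxel spacing, mm.
#' @slot sliceThickness slice thickness, mm.
#' @slot sliceIncrement slice spacing, mm (<= thickness allows overlap).
#' @slot supersampling integer >= 1, rasterisation oversampling per axis.
#' @slot psfSigma in-plane Gaussian PSF sigma, mm.
#' @slot noiseSigma additive Gaussian noise SD, HU.
#' @slot motionVelocity transverse motion speed, mm/s (blur along x).
#' @slot exposureTime effective per-slice acquisition time, s.
#' @slot jitterMM half-width of the random sub-voxel phantom translation
#'   between acquisitions, numeric(3), mm (0 = perfectly repositioned).
#' @slot marginMM grid margin around the inserts, mm.
#' @slot seed integer RNG seed; all randomness of one acquisition flows
#'   from it.
#' @slot maxVoxels supersampled-grid size budget (error when exceeded).
#' @slot calibration HA-to-HU affine map c(slope_hu_per_mg_cm3, offset_hu).
#' @export
setClass("PhantomSpec",
  representation(inserts = "list", backgroundHU = "numeric",
                 inPlaneSpacing = "numeric", sliceThickness = "numeric",
                 sliceIncrement = "numeric", supersampling = "integer",
                 psfSigma = "numeric", noiseSigma = "numeric",
                 motionVelocity = "numeric", exposureTime = "numeric",
                 jitterMM = "numeric", marginMM = "numeric", seed = "integer",
                 maxVoxels = "numeric", calibration = "numeric"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (!all(vapply(object@inserts, is, TRUE, class2 = "InsertSpec")))
    msg <- c(msg, "inserts must all be InsertSpec objects")
  if (object@inPlaneSpacing <= 0 || object@sliceThickness <= 0 ||
      object@sliceIncrement <= 0)
    msg <- c(msg, "spacings must be strictly positive")
  if (object@sliceIncrement > object@sliceThickness + 1e-9)
    msg <- c(msg, "sliceIncrement must not exceed sliceThickness")
  if (object@supersampling < 1L) msg <- c(msg, "supersampling must be >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@motionVelocity < 0) msg <- c(msg, "motionVelocity must be >= 0")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@exposureTime <= 0) msg <- c(msg, "exposureTime must be > 0")
  if (length(object@jitterMM) != 3L || any(object@jitterMM < 0))
    msg <- c(msg, "jitterMM must be 3 non-negative values")
  if (length(object@calibration) != 2L)
    msg <- c(msg, "calibration must be c(slope, offset)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults mirror a conventional calcium-scoring acquisition: 0.4 mm
#' in-plane spacing, 3 mm slice thickness and increment, a 0.6 mm PSF
#' sigma, and no motion.
#'
#' @param inserts list of [InsertSpec-class] objects.
#' @param backgroundHU background radiodensity in HU.
#' @param inPlaneSpacing,sliceThickness,sliceIncrement grid spacings, mm.
#' @param supersampling rasterisation factor per axis (integer >= 1).
#' @param psfSigma in-plane PSF sigma, mm.
#' @param noiseSigma additive noise SD, HU.
#' @param motionVelocity transverse motion speed, mm/s.
#' @param exposureTime effective per-slice acquisition time, s.
#' @param jitterMM per-axis half-width (mm) of the random phantom
#'   translation between acquisitions; scalar is recycled.
#' @param marginMM grid margin around the inserts, mm.
#' @param seed integer RNG seed.
#' @param maxVoxels supersampled grid budget.
#' @param calibration HA-to-HU map, c(slope, offset); see [haToHU()].
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(inserts = list(), backgroundHU = 0,
                        inPlaneSpacing = 0.4, sliceThickness = 3,
                        sliceIncrement = 3, supersampling = 8L,
                        psfSigma = 0.6, noiseSigma = 0, motionVelocity = 0,
                        exposureTime = 0.35, jitterMM = 0, marginMM = 6,
                        seed = 1L, maxVoxels = 2e8,
                        calibration = c(1.6, 0)) {
  if (length(jitterMM) == 1L) jitterMM <- rep(jitterMM, 3L)
  new("PhantomSpec", inserts = inserts, backgroundHU = backgroundHU,
      inPlaneSpacing = inPlaneSpacing, sliceThickness = sliceThickness,
      sliceIncrement = sliceIncrement, supersampling = as.integer(supersampling),
      psfSigma = psfSigma, noiseSigma = noiseSigma,
      motionVelocity = motionVelocity, exposureTime = exposureTime,
      jitterMM = as.numeric(jitterMM), marginMM = marginMM,
      seed = as.integer(seed), maxVoxels = maxVoxels,
      calibration = as.numeric(calibration))
}

#' GroundTruth: analytic and rasterised truth of a simulated acquisition
#'
#' @slot volumes data.frame with one row per insert: insert_id, shape,
#'   density, true_volume_mm3.
#' @slot occupancy list of fractional-occupancy arrays on the
#'   reconstruction grid, one per insert (values in [0, 1]).
#' @export
setClass("GroundTruth",
  representation(volumes = "data.frame", occupancy = "list"))

#' LesionSegmentation: per-lesion voxel sets and distance bounds
#'
#' Masks are stored as integer linear indices into the volume grid.
#'
#' @slot labelId lesion label (1 = largest initial component).
#' @slot dim integer(3) volume dimensions the indices refer to.
#' @slot initialIdx voxels of the >= 130 HU connected component.
#' @slot extendedIdx refined > 90 HU extension (disjoint from initial).
#' @slot backgroundIdx local background shell voxels.
#' @slot d1 largest interior distance of the initial mask, mm.
#' @slot d2 largest interior distance of the calcification mask, mm.
#' @export
setClass("LesionSegmentation",
  representation(labelId = "integer", dim = "integer", initialIdx = "integer",
                 extendedIdx = "integer", backgroundIdx = "integer",
                 d1 = "numeric", d2 = "numeric"))

setValidity("LesionSegmentation", function(object) {
  msg <- character()
  if (any(object@extendedIdx %in% object@initialIdx))
    msg <- c(msg, "extended mask must be disjoint from initial mask")
  calc <- c(object@initialIdx, object@extendedIdx)
  if (any(object@backgroundIdx %in% calc))
    msg <- c(msg, "background mask must be disjoint from calcification mask")
  nmax <- prod(object@dim)
  idx <- c(calc, object@backgroundIdx)
  if (length(idx) && (min(idx) < 1L || max(idx) > nmax))
    msg <- c(msg, "indices out of volume bounds")
  if (length(msg)) msg else TRUE
})

#' GaussianMixtureEstimate: two-component EM fit of lesion intensities
#'
#' Components are relabeled so the foreground (calcification) mean is the
#' larger one. FWHM of the background component is
#' \code{2 * sqrt(2 * log(2)) * sigmaB}.
#'
#' @slot muB,sigmaB background mean / SD, HU.
#' @slot muF,sigmaF foreground (calcification) mean / SD, HU.
#' @slot weights mixing proportions (background, foreground), sum 1.
#' @slot nIterations EM iterations used.
#' @slot converged TRUE when the log-likelihood gain fell below tol.
#' @slot logLik final log-likelihood.
#' @slot degenerate TRUE when a component collapsed onto the sigma floor.
#' @export
setClass("GaussianMixtureEstimate",
  representation(muB = "numeric", sigmaB = "numeric", muF = "numeric",
                 sigmaF = "numeric", weights = "numeric",
                 nIterations = "integer", converged = "logical",
                 logLik = "numeric", degenerate = "logical"))

setValidity("GaussianMixtureEstimate", function(object) {
  msg <- character()
  if (object@sigmaB <= 0 || object@sigmaF <= 0)
    msg <- c(msg, "component SDs must be positive")
  if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-8 ||
      any(object@weights <= 0))
    msg <- c(msg, "weights must be positive and sum to 1")
  if (object@muF < object@muB)
    msg <- c(msg, "components must be ordered with muF >= muB")
  if (length(msg)) msg else TRUE
})

#' LesionScore: per-lesion threshold, calcium fractions, and volumes
#'
#' @slot labelId lesion label.
#' @slot em the [GaussianMixtureEstimate-class] behind the threshold.
#' @slot thresholdHU per-lesion threshold muB + FWHM_B / 2, HU.
#' @slot xMin,xMax intensity scaling bounds of the scored lesion, HU.
#' @slot scoredIdx linear indices of the scored (supra-threshold) voxels.
#' @slot pvc per-voxel fractional calcium content over scoredIdx, in [0,1].
#' @slot nVoxels number of voxels in the initial (clinical) segmentation.
#' @slot ccsVolume clinical volume score: nVoxels * voxel volume, mm^3.
#' @slot pvcVolume partial-volume-corrected volume, sum(pvc) * voxel
#'   volume, mm^3.
#' @export
setClass("LesionScore",
  representation(labelId = "integer", em = "GaussianMixtureEstimate",
                 thresholdHU = "numeric", xMin = "numeric", xMax = "numeric",
                 scoredIdx = "integer", pvc = "numeric", nVoxels = "integer",
                 ccsVolume = "numeric", pvcVolume = "numeric"))

setValidity("LesionScore", function(object) {
  msg <- character()
  if (length(object@pvc) && (min(object@pvc) < -1e-12 ||
                             max(object@pvc) > 1 + 1e-12))
    msg <- c(msg, "pvc fractions must lie in [0, 1]")
  if (length(object@pvc) != length(object@scoredIdx))
    msg <- c(msg, "pvc and scoredIdx lengths differ")
  if (isTRUE(object@xMin > object@xMax))
    msg <- c(msg, "xMin must not exceed xMax")
  if (object@pvcVolume < 0) msg <- c(msg, "pvcVolume must be >= 0")
  if (length(msg)) msg else TRUE
})

#' ScanResult: all lesions of one scored scan
#'
#' @slot segmentations list of [LesionSegmentation-class].
#' @slot scores list of [LesionScore-class] (NULL entries for failed
#'   lesions).
#' @slot totals named numeric: total ccs and pvc volumes, mm^3.
#' @slot status per-lesion status string ("ok" or an error message).
#' @slot config the [RunConfig-class] used.
#' @export
setClass("ScanResult",
  representation(segmentations = "list", scores = "list", totals = "numeric",
                 status = "character", config = "ANY"))

#' AgreementStats: paired-measurement agreement summary
#'
#' @slot bias mean paired difference.
#' @slot loaLow,loaHigh 95% limits of agreement (bias +/- 1.96 SD).
#' @slot icc intraclass correlation ICC(2,1) (NA when not computed).
#' @slot iccLow,iccHigh 95% CI of the ICC (F-distribution method).
#' @slot nPairs number of pairs.
#' @export
setClass("AgreementStats",
  representation(bias = "numeric", loaLow = "numeric", loaHigh = "numeric",
                 icc = "numeric", iccLow = "numeric", iccHigh = "numeric",
                 nPairs = "integer"))

setValidity("AgreementStats", function(object) {
  msg <- character()
  if (isTRUE(object@loaLow > object@bias) || isTRUE(object@bias > object@loaHigh))
    msg <- c(msg, "limits of agreement must bracket the bias")
  if (!is.na(object@icc) && (object@icc < -1 - 1e-9 || object@icc > 1 + 1e-9))
    msg <- c(msg, "icc must lie in [-1, 1]")
  if (!is.na(object@icc) && !is.na(object@iccLow) &&
      (isTRUE(object@iccLow > object@icc + 1e-9) ||
       isTRUE(object@iccHigh < object@icc - 1e-9)))
    msg <- c(msg, "icc CI must bracket the estimate")
  if (length(msg)) msg else TRUE
})

#' RunConfig: scoring configuration
#'
#' @slot detectionHU initial lesion detection threshold (clinical 130 HU).
#' @slot extensionHU lesion extension threshold (90 HU); must be below
#'   detectionHU.
#' @slot minLesionVoxels minimum initial component size kept.
#' @slot emTol EM log-likelihood convergence tolerance.
#' @slot emMaxIter EM iteration cap.
#' @slot sigmaFloor component SD floor in HU.
#' @slot xminMode how X_min of the intensity scaling is chosen:
#'   "supra_threshold" (minimum over scored voxels, default),
#'   "literal_lesion_min" (minimum over the whole calcification mask), or
#'   "threshold" (the EM threshold itself).
#' @export
setClass("RunConfig",
  representation(detectionHU = "numeric", extensionHU = "numeric",
                 minLesionVoxels = "integer", emTol = "numeric",
                 emMaxIter = "integer", sigmaFloor = "numeric",
                 xminMode = "character"))

setValidity("RunConfig", function(object) {
  msg <- character()
  if (!is.finite(object@detectionHU) || !is.finite(object@extensionHU))
    msg <- c(msg, "thresholds must be finite")
  if (object@extensionHU >= object@detectionHU)
    msg <- c(msg, "extensionHU must be strictly below detectionHU")
  if (object@minLesionVoxels < 1L) msg <- c(msg, "minLesionVoxels must be >= 1")
  if (object@emTol <= 0 || object@emMaxIter < 1L)
    msg <- c(msg, "invalid EM settings")
  if (!object@xminMode %in% c("supra_threshold", "literal_lesion_min", "threshold"))
    msg <- c(msg, "unknown xminMode")
  if (length(msg)) msg else TRUE
})

#' Construct a RunConfig
#'
#' @param detectionHU,extensionHU detection / extension thresholds, HU.
#' @param minLesionVoxels minimum initial component size.
#' @param emTol,emMaxIter EM stopping rule.
#' @param sigmaFloor EM component SD floor, HU.
#' @param xminMode intensity scaling lower bound mode, see
#'   [RunConfig-class].
#' @return A [RunConfig-class] object.
#' @examples
#' runConfig()
#' @export
runConfig <- function(detectionHU = 130, extensionHU = 90,
                      minLesionVoxels = 1L, emTol = 1e-6, emMaxIter = 200L,
                      sigmaFloor = 0.5, xminMode = "supra_threshold") {
  new("RunConfig", detectionHU = detectionHU, extensionHU = extensionHU,
      minLesionVoxels = as.integer(minLesionVoxels), emTol = emTol,
      emMaxIter = as.integer(emMaxIter), sigmaFloor = sigmaFloor,
      xminMode = xminMode)
}
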