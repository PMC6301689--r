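## Accessor generics. Slots are never reached into from user code.

#' @rdname CTVolume-class
#' @param x,object a pvcscore S4 object.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname CTVolume-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname CTVolume-class
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname CTVolume-class
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' @rdname InsertSpec-class
#' @param x an [InsertSpec-class].
#' @export
setGeneric("trueVolume", function(x) standardGeneric("trueVolume"))

#' @rdname LesionSegmentation-class
#' @param x a [LesionSegmentation-class].
#' @export
setGeneric("initialIndices", function(x) standardGeneric("initialIndices"))
#' @rdname LesionSegmentation-class
#' @export
setGeneric("extendedIndices", function(x) standardGeneric("extendedIndices"))
#' @rdname LesionSegmentation-class
#' @export
setGeneric("backgroundIndices", function(x) standardGeneric("backgroundIndices"))
#' @rdname LesionSegmentation-class
#' @export
setGeneric("calcificationIndices", function(x) standardGeneric("calcificationIndices"))

#' @rdname ScanResult-class
#' @param x a [ScanResult-class].
#' @export
setGeneric("ccsTotal", function(x) standardGeneric("ccsTotal"))
#' @rdname ScanResult-class
#' @export
setGeneric("pvcTotal", function(x) standardGeneric("pvcTotal"))
#' @rdname ScanResult-class
#' @export
setGeneric("lesionScores", function(x) standardGeneric("lesionScores"))
#' @rdname ScanResult-class
#' @export
setGeneric("lesionSegmentations", function(x) standardGeneric("lesionSegmentations"))

setMethod("intensities", "CTVolume", function(x) x@intensities)
setMethod("spacing", "CTVolume", function(x) x@spacing)
setMethod("origin", "CTVolume", function(x) x@origin)
setMethod("voxelVolume", "CTVolume", function(x) prod(x@spacing))
#' @rdname CTVolume-class
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@intensities))

setMethod("trueVolume", "InsertSpec", function(x) {
  if (x@shape == "cylinder") cylinderVolume(x@diameter, x@length)
  else segmentVolume(x@radius, x@capHeight, x@length)
})

setMethod("initialIndices", "LesionSegmentation", function(x) x@initialIdx)
setMethod("extendedIndices", "LesionSegmentation", function(x) x@extendedIdx)
setMethod("backgroundIndices", "LesionSegmentation", function(x) x@backgroundIdx)
setMethod("calcificationIndices", "LesionSegmentation",
          function(x) sort(c(x@initialIdx, x@extendedIdx)))

setMethod("ccsTotal", "ScanResult", function(x) unname(x@totals["ccs"]))
setMethod("pvcTotal", "ScanResult", function(x) unname(x@totals["pvc"]))
setMethod("lesionScores", "ScanResult", function(x) x@scores)
setMethod("lesionSegmentations", "ScanResult", function(x) x@segmentations)

setMethod("show", "CTVolume", function(object) {
  d <- dim(object)
  cat(sprintf("CTVolume %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(object@intensities),
              max(object@intensities)))
})

setMethod("show", "InsertSpec", function(object) {
  if (object@shape == "cylinder")
    cat(sprintf("cylinder insert d=%.2f mm, L=%.2f mm, %g mg/cm^3 (%.1f mm^3)\n",
                object@diameter, object@length, object@density,
                trueVolume(object)))
  else
    cat(sprintf(
      "segment insert r=%.2f mm, h=%.2f mm, L=%.2f mm, %g mg/cm^3 (%.1f mm^3)\n",
      object@radius, object@capHeight, object@length, object@density,
      trueVolume(object)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: %d insert(s), background %g HU, %g/%g/%g mm grid\n",
    length(object@inserts), object@backgroundHU, object@inPlaneSpacing,
    object@sliceThickness, object@sliceIncrement))
  cat(sprintf("  PSF sigma %g mm, noise %g HU, motion %g mm/s, seed %d\n",
              object@psfSigma, object@noiseSigma, object@motionVelocity,
              object@seed))
})

setMethod("show", "GaussianMixtureEstimate", function(object) {
  cat(sprintf(
    "2-component Gaussian mixture: B ~ N(%.1f, %.1f^2), F ~ N(%.1f, %.1f^2)\n",
    object@muB, object@sigmaB, object@muF, object@sigmaF))
  cat(sprintf("  weights %.3f/%.3f, %d iterations, converged: %s%s\n",
              object@weights[1], object@weights[2], object@nIterations,
              object@converged, if (object@degenerate) " (degenerate)" else ""))
})

setMethod("show", "LesionScore", function(object) {
  cat(sprintf(
    "Lesion %d: threshold %.1f HU, C-CS %.2f mm^3, PVC-CS %.2f mm^3\n",
    object@labelId, object@thresholdHU, object@ccsVolume, object@pvcVolume))
})

setMethod("show", "ScanResult", function(object) {
  n <- length(object@scores)
  cat(sprintf("ScanResult: %d lesion(s)\n", n))
  cat(sprintf("  total C-CS  %.2f mm^3\n", object@totals["ccs"]))
  cat(sprintf("  total PVC-CS %.2f mm^3\n", object@totals["pvc"]))
})

setMethod("show", "AgreementStats", function(object) {
  cat(sprintf("AgreementStats over %d pairs\n", object@nPairs))
  cat(sprintf("  bias %.4g, limits of agreement [%.4g, %.4g]\n",
              object@bias, object@loaLow, object@loaHigh))
  if (!is.na(object@icc))
    cat(sprintf("  ICC(2,1) %.4f, 95%% CI [%.4f, %.4f]\n", object@icc,
                object@iccLow, object@iccHigh))
})
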