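## Lesion segmentation: clinical 130 HU detection, 90 HU extension bounded
## by the interior distance d1 of the initial mask, and a background shell
## bounded by the interior distance d2 of the calcification mask. All
## distances are voxel-center to voxel-center in mm, with the anisotropic
## (typically dz >> dx) spacing honoured exactly.

.asMask <- function(idx, dims) {
  m <- array(FALSE, dims)
  m[idx] <- TRUE
  m
}

#' Anisotropic Euclidean distance map of a voxel mask
#'
#' Distances are measured in mm between voxel centers, weighting each axis
#' by its spacing, so a single slice step at 3 mm slice spacing counts 3 mm.
#' \code{direction = "interior"} returns, for every mask voxel, the
#' distance to the nearest non-mask voxel center (0 elsewhere);
#' \code{"exterior"} returns, for every non-mask voxel, the distance to the
#' nearest mask voxel center (0 on the mask).
#'
#' @param mask 3D logical array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param direction "interior" or "exterior".
#' @return Numeric array of distances (mm) with the mask's dimensions.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' anisotropicDistanceMap(m, c(1, 1, 3), "interior")[2, 2, 2]  # 1
#' @export
anisotropicDistanceMap <- function(mask, spacing,
                                   direction = c("interior", "exterior")) {
  direction <- match.arg(direction)
  dims <- dim(mask)
  if (length(dims) != 3L) stop("mask must be a 3D array")
  if (direction == "interior") {
    if (!any(mask)) stop("interior distance of an empty mask is undefined")
    d <- array(.edt3d(!mask, as.integer(dims), as.numeric(spacing)), dims)
    d[!mask] <- 0
  } else {
    d <- array(.edt3d(mask, as.integer(dims), as.numeric(spacing)), dims)
    d[mask] <- 0
  }
  d
}

#' Detect CAC lesions by clinical intensity thresholding
#'
#' Maximal 26-connected components of the voxel set at or above the
#' detection threshold (clinically 130 HU), sorted by size, largest first.
#'
#' @param volume a [CTVolume-class].
#' @param detectionHU detection threshold in HU.
#' @param minVoxels minimum component size retained.
#' @param roi optional logical array restricting detection.
#' @return List of integer vectors of linear voxel indices (possibly
#'   empty).
#' @export
detectLesions <- function(volume, detectionHU = 130, minVoxels = 1L,
                          roi = NULL) {
  hu <- intensities(volume)
  m <- hu >= detectionHU
  if (!is.null(roi)) m <- m & roi
  if (!any(m)) return(list())
  lab <- .label26(m, as.integer(dim(hu)))
  idx <- which(lab > 0L)
  comps <- split(idx, lab[idx])
  sizes <- lengths(comps)
  comps <- comps[sizes >= minVoxels]
  if (!length(comps)) return(list())
  ord <- order(lengths(comps), vapply(comps, min, 0L), decreasing = c(TRUE, FALSE),
               method = "radix")
  unname(comps[ord])
}

#' Extend a lesion below the detection threshold
#'
#' Voxels strictly above the extension threshold (90 HU) that are
#' 26-connected to the initial segmentation may still contain calcium.
#' The candidate set is grown from the initial mask through the
#' supra-extension-threshold voxels and then refined by discarding
#' candidates farther than d1 from the initial segmentation, where d1 is
#' the largest interior distance of the initial mask (its "center" depth).
#'
#' @param volume a [CTVolume-class].
#' @param initialIdx integer indices of the initial (>= 130 HU) component.
#' @param extensionHU extension threshold in HU.
#' @return list(extendedIdx = integer indices disjoint from the initial
#'   mask, d1 = largest interior distance of the initial mask in mm).
#' @export
extendLesion <- function(volume, initialIdx, extensionHU = 90) {
  if (!length(initialIdx)) stop("initial mask must be non-empty")
  hu <- intensities(volume)
  dims <- dim(hu)
  sp <- spacing(volume)
  init <- .asMask(initialIdx, dims)

  d1 <- max(anisotropicDistanceMap(init, sp, "interior"))

  region <- (hu > extensionHU) | init
  lab <- .label26(region, as.integer(dims))
  keepLab <- lab[initialIdx[1]]
  cand <- which(lab == keepLab)
  cand <- cand[!(cand %in% initialIdx)]
  if (length(cand)) {
    dext <- anisotropicDistanceMap(init, sp, "exterior")
    cand <- cand[dext[cand] <= d1 + 1e-9]
  }
  list(extendedIdx = as.integer(cand), d1 = d1)
}

#' Define the local background of a calcification
#'
#' The background shell holds the non-calcification voxels within d2 of
#' the calcification, where d2 is the largest interior distance of the
#' calcification mask. Voxels belonging to another lesion's calcification
#' mask are excluded so that calcium never contaminates the background
#' intensity distribution.
#'
#' @param volume a [CTVolume-class].
#' @param calcIdx calcification mask (initial + extended) indices.
#' @param otherCalcIdx indices of all other lesions' calcification masks.
#' @return list(backgroundIdx, d2).
#' @export
defineBackground <- function(volume, calcIdx, otherCalcIdx = integer()) {
  if (!length(calcIdx)) stop("calcification mask must be non-empty")
  dims <- dim(volume)
  sp <- spacing(volume)
  calc <- .asMask(calcIdx, dims)
  d2 <- max(anisotropicDistanceMap(calc, sp, "interior"))
  dext <- anisotropicDistanceMap(calc, sp, "exterior")
  bg <- which(!calc & dext <= d2 + 1e-9 & dext > 0)
  bg <- bg[!(bg %in% otherCalcIdx)]
  list(backgroundIdx = as.integer(bg), d2 = d2)
}

#' Segment all lesions of a scan
#'
#' Runs detection, extension and background definition for every lesion.
#'
#' @param volume a [CTVolume-class].
#' @param config a [RunConfig-class].
#' @param roi optional logical array restricting detection.
#' @return List of [LesionSegmentation-class], ordered by initial size.
#' @export
segmentLesions <- function(volume, config = runConfig(), roi = NULL) {
  initial <- detectLesions(volume, config@detectionHU,
                           config@minLesionVoxels, roi)
  if (!length(initial)) return(list())
  ext <- lapply(initial, function(ii)
    extendLesion(volume, ii, config@extensionHU))
  calc <- lapply(seq_along(initial), function(i)
    c(initial[[i]], ext[[i]]$extendedIdx))
  dims <- dim(volume)
  lapply(seq_along(initial), function(i) {
    others <- unlist(calc[-i], use.names = FALSE)
    bg <- defineBackground(volume, calc[[i]], others)
    new("LesionSegmentation", labelId = as.integer(i),
        dim = as.integer(dims),
        initialIdx = as.integer(initial[[i]]),
        extendedIdx = ext[[i]]$extendedIdx,
        backgroundIdx = bg$backgroundIdx,
        d1 = ext[[i]]$d1, d2 = bg$d2)
  })
}
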