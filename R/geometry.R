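#' Analytic volume of a cylindrical calcification insert
#'
#' @param diameter cylinder diameter in mm.
#' @param length cylinder length in mm.
#' @return Volume in mm^3, \eqn{\pi (d/2)^2 L}.
#' @examples
#' round(cylinderVolume(5, 5), 1)   # 98.2
#' round(cylinderVolume(3, 3), 1)   # 21.2
#' round(cylinderVolume(1, 1), 1)   # 0.8
#' @export
cylinderVolume <- function(diameter, length) {
  if (any(diameter < 0) || any(length < 0))
    stop("diameter and length must be non-negative")
  pi * (diameter / 2)^2 * length
}

#' Analytic volume of a circular-segment calcification insert
#'
#' The cross-section is a circular segment: the part of a disk of radius
#' \code{radius} on one side of a chord at distance \code{radius -
#' capHeight} from the center. \code{capHeight = 2 * radius} recovers the
#' full cylinder, \code{capHeight = radius} the half cylinder.
#'
#' @param radius disk radius in mm.
#' @param capHeight segment height in mm, 0 <= h <= 2 * radius.
#' @param length extrusion length in mm.
#' @return Volume in mm^3: \eqn{L (R^2 \arccos((R-h)/R) - (R-h)\sqrt{2Rh - h^2})}.
#' @examples
#' round(segmentVolume(2, 2, 10), 1)    # 62.8 (half cylinder)
#' round(segmentVolume(2, 1, 10), 1)    # 24.6
#' round(segmentVolume(2, 0.5, 10), 1)  # 9.1
#' @export
segmentVolume <- function(radius, capHeight, length) {
  if (any(radius < 0) || any(length < 0))
    stop("radius and length must be non-negative")
  if (any(capHeight < 0) || any(capHeight > 2 * radius + 1e-12))
    stop("cap height must satisfy 0 <= h <= 2 * radius")
  r <- radius; h <- capHeight
  a <- ifelse(r == 0, 0,
              r^2 * acos(pmin(1, pmax(-1, (r - h) / r))) -
                (r - h) * sqrt(pmax(0, 2 * r * h - h^2)))
  a * length
}

#' Map hydroxyapatite density to CT intensity
#'
#' Affine calibration from insert HA density (mg/cm^3) to HU at 120 kVp.
#' The default slope of 1.6 HU per mg/cm^3 places the common insert
#' densities 200/400/800 mg/cm^3 at 320/640/1280 HU, all above the 130 HU
#' detection threshold before blurring.
#'
#' @param density HA density in mg/cm^3 (non-negative).
#' @param calibration numeric(2): c(slope_hu_per_mg_cm3, offset_hu).
#' @return Insert intensity in HU.
#' @examples
#' haToHU(c(200, 400, 800))
#' @export
haToHU <- function(density, calibration = c(1.6, 0)) {
  if (any(density < 0)) stop("density must be non-negative")
  calibration[1] * density + calibration[2]
}
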