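## Volumetric I/O. NIfTI goes through RNifti; MetaImage (.mha/.mhd) is a
## plain key-value header plus a raw block and is read/written directly
## (no installed R package handles it). Axis order is kept as stored
## (x, y, z with z the slice direction); no reorientation is attempted.

.metaTypes <- c(MET_UCHAR = "integer", MET_SHORT = "integer",
                MET_INT = "integer", MET_FLOAT = "double",
                MET_DOUBLE = "double")
.metaSizes <- c(MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
                MET_FLOAT = 4L, MET_DOUBLE = 8L)

.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("MetaImage header ended before ElementDataFile")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (k in c("DimSize", "ElementSpacing", "ElementType"))
    if (is.null(hdr[[k]])) stop("MetaImage header missing ", k)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  org <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else rep(0, length(dims))
  type <- hdr$ElementType
  if (!type %in% names(.metaTypes)) stop("unsupported ElementType ", type)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, .metaTypes[[type]], n = n, size = .metaSizes[[type]],
                    endian = "little")
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stop("MetaImage data file not found: ", rawPath)
    vals <- readBin(rawPath, .metaTypes[[type]], n = n,
                    size = .metaSizes[[type]], endian = "little")
  }
  if (length(vals) != n)
    stop("truncated MetaImage data: expected ", n, " values, read ",
         length(vals))
  CTVolume(array(as.numeric(vals), dims), spacing = sp, origin = org)
}

.writeMetaImage <- function(volume, path, type = "MET_FLOAT") {
  dims <- dim(volume)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  dataFile <- if (local) "LOCAL" else
    sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementSpacing =", paste(spacing(volume), collapse = " ")),
    paste("Offset =", paste(origin(volume), collapse = " ")),
    "ElementByteOrderMSB = False",
    paste("ElementType =", type),
    paste("ElementDataFile =", dataFile))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vals <- as.numeric(intensities(volume))
  if (local) {
    writeBin(vals, con, size = .metaSizes[[type]], endian = "little")
  } else {
    writeBin(vals, file.path(dirname(path), dataFile),
             size = .metaSizes[[type]], endian = "little")
  }
  invisible(path)
}

#' Read a CT volume from NIfTI or MetaImage
#'
#' NIfTI files (.nii, .nii.gz) are read with RNifti, which applies any
#' intensity rescale slope/intercept, so values arrive in HU; the voxel
#' spacing comes from pixdim and the origin from the stored transform's
#' translation. MetaImage files (.mha single-file or .mhd + .raw) are read
#' directly. Axis order is taken as stored, (x, y, z).
#'
#' @param path path to a .nii, .nii.gz, .mha or .mhd file.
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    return(.readMetaImage(path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unrecognised volume format: ", path,
         " (supported: .nii, .nii.gz, .mha, .mhd)")
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L) stop("expected a 3D volume, got ", length(dims),
                               " dimensions")
  sp <- attr(img, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(img)
  sp <- abs(sp[seq_len(3)])
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in NIfTI header")
  xf <- try(RNifti::xform(img), silent = TRUE)
  org <- if (!inherits(xf, "try-error")) xf[seq_len(3), 4] else c(0, 0, 0)
  CTVolume(array(as.numeric(img), dims), spacing = sp, origin = org)
}

#' Write a CT volume to NIfTI or MetaImage
#'
#' The format follows the file extension. NIfTI stores the spacing in
#' pixdim and the origin in the sform translation; MetaImage stores them
#' as ElementSpacing / Offset (32-bit float data, little endian).
#'
#' @param volume a [CTVolume-class].
#' @param path output path ending in .nii, .nii.gz, .mha or .mhd.
#' @return The path, invisibly.
#' @examples
#' v <- CTVolume(array(rnorm(8), c(2, 2, 2)), spacing = c(0.4, 0.4, 3))
#' p <- tempfile(fileext = ".nii.gz")
#' writeVolume(v, p)
#' all.equal(intensities(readVolume(p)), intensities(v), tolerance = 1e-6)
#' @export
writeVolume <- function(volume, path) {
  stopifnot(is(volume, "CTVolume"))
  if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE))
    return(.writeMetaImage(volume, path))
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE))
    stop("unrecognised volume format: ", path)
  sp <- spacing(volume)
  affine <- diag(c(sp, 1))
  affine[seq_len(3), 4] <- origin(volume)
  img <- RNifti::asNifti(intensities(volume))
  RNifti::pixdim(img) <- sp
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a per-lesion scoring report as CSV
#'
#' One row per scored lesion: lesion id, initial voxel count, background
#' mean and SD, per-lesion threshold, intensity scaling bounds, and the
#' clinical and corrected volumes.
#'
#' @param result a [ScanResult-class].
#' @param path output CSV path.
#' @return The report data.frame, invisibly.
#' @export
writeLesionReport <- function(result, path) {
  scores <- lesionScores(result)
  ok <- !vapply(scores, is.null, TRUE)
  df <- do.call(rbind, lapply(scores[ok], function(s)
    data.frame(lesion_id = s@labelId, n_voxels = s@nVoxels,
               mu_B = s@em@muB, sigma_B = s@em@sigmaB,
               threshold_hu = s@thresholdHU, x_min = s@xMin, x_max = s@xMax,
               ccs_volume_mm3 = s@ccsVolume, pvc_volume_mm3 = s@pvcVolume)))
  if (is.null(df))
    df <- data.frame(lesion_id = integer(), n_voxels = integer(),
                     mu_B = numeric(), sigma_B = numeric(),
                     threshold_hu = numeric(), x_min = numeric(),
                     x_max = numeric(), ccs_volume_mm3 = numeric(),
                     pvc_volume_mm3 = numeric())
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Serialise a phantom specification to a YAML config file
#'
#' The schema is a flat key-value map of the acquisition settings plus an
#' \code{inserts} sequence, each entry holding shape, dimensions (mm),
#' density (mg/cm^3), center and orientation. [readPhantomSpec()] inverts
#' it exactly.
#'
#' @param spec a [PhantomSpec-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writePhantomSpec <- function(spec, path) {
  ins <- lapply(spec@inserts, function(i) list(
    shape = i@shape, diameter = i@diameter, radius = i@radius,
    capHeight = i@capHeight, length = i@length, density = i@density,
    center = i@center, theta = i@theta))
  lst <- list(backgroundHU = spec@backgroundHU,
              inPlaneSpacing = spec@inPlaneSpacing,
              sliceThickness = spec@sliceThickness,
              sliceIncrement = spec@sliceIncrement,
              supersampling = spec@supersampling,
              psfSigma = spec@psfSigma, noiseSigma = spec@noiseSigma,
              motionVelocity = spec@motionVelocity,
              exposureTime = spec@exposureTime, jitterMM = spec@jitterMM,
              marginMM = spec@marginMM, seed = spec@seed,
              maxVoxels = spec@maxVoxels, calibration = spec@calibration,
              inserts = ins)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @return \code{readPhantomSpec}: a [PhantomSpec-class].
#' @export
readPhantomSpec <- function(path) {
  lst <- yaml::read_yaml(path)
  inserts <- lapply(lst$inserts, function(i) {
    if (i$shape == "cylinder")
      cylinderInsert(i$diameter, i$length, i$density, unlist(i$center))
    else
      segmentInsert(i$radius, i$capHeight, i$length, i$density,
                    unlist(i$center), i$theta)
  })
  phantomSpec(inserts, backgroundHU = lst$backgroundHU,
              inPlaneSpacing = lst$inPlaneSpacing,
              sliceThickness = lst$sliceThickness,
              sliceIncrement = lst$sliceIncrement,
              supersampling = lst$supersampling, psfSigma = lst$psfSigma,
              noiseSigma = lst$noiseSigma,
              motionVelocity = lst$motionVelocity,
              exposureTime = lst$exposureTime, jitterMM = unlist(lst$jitterMM),
              marginMM = lst$marginMM, seed = lst$seed,
              maxVoxels = lst$maxVoxels, calibration = unlist(lst$calibration))
}
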