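## Evaluation machinery: volume ratios, median/range over repeated
## acquisitions, min-max scaling across paired reconstructions,
## Bland-Altman limits of agreement, and ICC(2,1) with the F-based CI.

#' Ratio of a measured to a reference volume
#'
#' @param measured measured volume, mm^3.
#' @param reference reference (true) volume, mm^3; must be positive.
#' @return measured / reference.
#' @examples
#' volumeRatio(213, 96.5)
#' @export
volumeRatio <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference volume must be positive")
  measured / reference
}

#' Median and range of repeated measurements
#'
#' @param values non-empty numeric vector.
#' @return Named numeric c(median, min, max); the median is the sample
#'   median (mean of the middle two for even n).
#' @examples
#' medianRange(c(1, 2, 3, 4))
#' @export
medianRange <- function(values) {
  if (!length(values)) stop("values must be non-empty")
  c(median = median(values), min = min(values), max = max(values))
}

#' Min-max scale volumes against a reference set
#'
#' Divides every volume by the maximum of the reference set, so the
#' largest reference volume maps to exactly 1. In a paired-reconstruction
#' comparison the reference set is the soft-kernel volumes of the same
#' scoring method.
#'
#' @param volumes numeric vector to scale.
#' @param reference numeric vector whose maximum defines the scale;
#'   defaults to \code{volumes}.
#' @return Scaled volumes.
#' @export
minmaxScaleVolumes <- function(volumes, reference = volumes) {
  m <- max(reference)
  if (!is.finite(m) || m <= 0)
    stop("reference set must contain a positive maximum")
  volumes / m
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are a - b (by convention soft minus sharp); the bias is
#' their mean and the 95% limits of agreement are bias +/- 1.96 times the
#' sample SD (n - 1 denominator).
#'
#' @param a,b equal-length paired numeric vectors, n >= 2.
#' @return An [AgreementStats-class] (ICC slots NA).
#' @examples
#' blandAltman(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' @export
blandAltman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("need at least two pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  new("AgreementStats", bias = bias, loaLow = bias - 1.96 * s,
      loaHigh = bias + 1.96 * s, icc = NA_real_, iccLow = NA_real_,
      iccHigh = NA_real_, nPairs = length(a))
}

## Mean squares of the two-way layout (n subjects x k raters).
.meanSquares <- function(x) {
  n <- nrow(x); k <- ncol(x)
  gm <- mean(x)
  rm <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  list(n = n, k = k, msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random effects, absolute agreement, single measurement: the
#' paired reconstructions are treated as random "raters" of one true
#' quantity. The confidence interval uses the F-distribution method
#' (McGraw & Wong).
#'
#' @param a,b paired numeric vectors (two raters), n >= 5 for a
#'   meaningful CI.
#' @param conf confidence level.
#' @return An [AgreementStats-class] with bias/LoA of a - b and the ICC
#'   with its CI.
#' @examples
#' set.seed(1); a <- rnorm(20); iccAgreement(a, a + rnorm(20, 0, 0.1))
#' @export
iccAgreement <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  x <- cbind(a, b)
  if (nrow(x) < 2L) stop("need at least two pairs")
  if (var(as.numeric(x)) == 0)
    stop("zero total variance: ICC is undefined")
  ms <- .meanSquares(x)
  n <- ms$n; k <- ms$k
  icc <- (ms$msr - ms$mse) /
    (ms$msr + (k - 1) * ms$mse + (k / n) * (ms$msc - ms$mse))

  alpha <- 1 - conf
  aa <- (k * icc) / (n * (1 - icc))
  bb <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  if (!is.finite(aa) || !is.finite(bb)) {        # icc == 1 exactly
    lo <- hi <- icc
  } else {
    v <- (aa * ms$msc + bb * ms$mse)^2 /
      ((aa * ms$msc)^2 / (k - 1) + (bb * ms$mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (ms$msr - fl * ms$mse) /
      (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
    hi <- n * (fu * ms$msr - ms$mse) /
      (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  }
  ba <- blandAltman(a, b)
  new("AgreementStats", bias = ba@bias, loaLow = ba@loaLow,
      loaHigh = ba@loaHigh, icc = icc, iccLow = min(lo, icc),
      iccHigh = max(hi, icc), nPairs = n)
}

## Attribute each detected lesion to the ground-truth insert with the
## largest fractional-occupancy overlap of its initial mask; lesions with
## no overlap stay unmatched (NA).
.matchLesions <- function(result, truth) {
  segs <- lesionSegmentations(result)
  vapply(segs, function(sg) {
    ov <- vapply(truth@occupancy, function(occ)
      sum(occ[initialIndices(sg)]), 0)
    if (!length(ov) || max(ov) <= 0) NA_integer_ else which.max(ov)
  }, 1L)
}

#' Paired sharp/soft reconstruction agreement study
#'
#' Simulates \code{nPairs} randomised single-insert phantoms (cylinder
#' diameter 2.5-5 mm, length 2.5-6 mm, HA density 200/400/800 mg/cm^3 in
#' a 50 HU blood-equivalent background), reconstructs each acquisition
#' with a sharp and a soft kernel surrogate, scores all volumes with both
#' methods, min-max scales each method against its soft-kernel maximum,
#' and summarises soft-vs-sharp agreement with Bland-Altman and ICC(2,1).
#'
#' @param nPairs number of paired reconstructions.
#' @param seed base RNG seed (geometry and acquisitions).
#' @param sharp,soft kernel surrogates, c(psf = mm, noise = HU).
#' @param config a [RunConfig-class].
#' @param supersampling rasterisation factor.
#' @return list(perPair = data.frame of raw and scaled volumes,
#'   ccs =, pvc = [AgreementStats-class]).
#' @export
runKernelAgreementStudy <- function(nPairs = 50, seed = 1L,
                                    sharp = c(psf = 0.4, noise = 18),
                                    soft = c(psf = 0.8, noise = 8),
                                    config = runConfig(),
                                    supersampling = 4L) {
  set.seed(seed)
  geom <- data.frame(diameter = runif(nPairs, 2.5, 5),
                     length = runif(nPairs, 2.5, 6),
                     density = sample(c(200, 400, 800), nPairs, TRUE))
  res <- lapply(seq_len(nPairs), function(i) {
    spec <- phantomSpec(list(cylinderInsert(geom$diameter[i], geom$length[i],
                                            geom$density[i])),
                        backgroundHU = 50, supersampling = supersampling,
                        marginMM = 5, seed = seed + i)
    pair <- simulatePairedReconstructions(spec, sharp = sharp, soft = soft)
    rSoft <- scoreScan(pair$soft, config)
    rSharp <- scoreScan(pair$sharp, config)
    c(ccs_soft = ccsTotal(rSoft), ccs_sharp = ccsTotal(rSharp),
      pvc_soft = pvcTotal(rSoft), pvc_sharp = pvcTotal(rSharp))
  })
  df <- cbind(geom, do.call(rbind, res))
  df$ccs_soft_scaled <- minmaxScaleVolumes(df$ccs_soft)
  df$ccs_sharp_scaled <- minmaxScaleVolumes(df$ccs_sharp, df$ccs_soft)
  df$pvc_soft_scaled <- minmaxScaleVolumes(df$pvc_soft)
  df$pvc_sharp_scaled <- minmaxScaleVolumes(df$pvc_sharp, df$pvc_soft)
  list(perPair = df,
       ccs = iccAgreement(df$ccs_soft_scaled, df$ccs_sharp_scaled),
       pvc = iccAgreement(df$pvc_soft_scaled, df$pvc_sharp_scaled))
}

#' Run a repeated-acquisition phantom experiment
#'
#' Simulates \code{repeats} seeded acquisitions of a replica phantom,
#' scores each with C-CS and PVC-CS, attributes every detected lesion to
#' its ground-truth insert, and aggregates measured volumes per insert and
#' per HA density group (the layout of typical phantom evaluation tables:
#' per-density median and range over acquisitions, plus measured/true
#' ratios).
#'
#' @param preset "ceora" or "sati".
#' @param ring extension ring for the ceora preset.
#' @param velocity motion speed (mm/s) for the sati preset.
#' @param repeats number of simulated acquisitions.
#' @param seed base RNG seed; acquisition r uses seed + r - 1.
#' @param config a [RunConfig-class].
#' @param supersampling rasterisation factor.
#' @param ... further arguments to [makeCeoraSpec()] / [makeSatiSpec()].
#' @return A list with \code{perInsert} (data.frame: repeat, insert,
#'   shape, density, true volume, detected flag, ccs and pvc volumes),
#'   \code{perDensity} (data.frame: density, detected true volume, ccs and
#'   pvc median/min/max over repeats), and \code{truthVolumes}.
#' @export
runPhantomExperiment <- function(preset = c("ceora", "sati"), ring = "none",
                                 velocity = 0, repeats = 5, seed = 1L,
                                 config = runConfig(), supersampling = 8L,
                                 ...) {
  preset <- match.arg(preset)
  rows <- list()
  truthVols <- NULL
  for (r in seq_len(repeats)) {
    spec <- if (preset == "ceora")
      makeCeoraSpec(ring, seed = seed + r - 1L, supersampling = supersampling,
                    ...)
    else
      makeSatiSpec(velocity, seed = seed + r - 1L,
                   supersampling = supersampling, ...)
    sim <- simulateAcquisition(spec)
    res <- scoreScan(sim$volume, config)
    truthVols <- sim$truth@volumes
    match <- .matchLesions(res, sim$truth)
    scores <- lesionScores(res)
    ccs <- pvc <- rep(0, nrow(truthVols))
    for (i in seq_along(scores)) {
      if (is.null(scores[[i]]) || is.na(match[i])) next
      ccs[match[i]] <- ccs[match[i]] + scores[[i]]@ccsVolume
      pvc[match[i]] <- pvc[match[i]] + scores[[i]]@pvcVolume
    }
    rows[[r]] <- data.frame(repeat_id = r, insert_id = truthVols$insert_id,
                            shape = truthVols$shape,
                            density = truthVols$density,
                            true_volume_mm3 = truthVols$true_volume_mm3,
                            detected = ccs > 0,
                            ccs_mm3 = ccs, pvc_mm3 = pvc)
  }
  perInsert <- do.call(rbind, rows)

  dens <- sort(unique(perInsert$density), decreasing = TRUE)
  perDensity <- do.call(rbind, lapply(dens, function(d) {
    sub <- perInsert[perInsert$density == d, ]
    byRep <- sapply(split(sub, sub$repeat_id), function(s)
      c(ccs = sum(s$ccs_mm3), pvc = sum(s$pvc_mm3),
        detTrue = sum(s$true_volume_mm3[s$detected])))
    mrC <- medianRange(byRep["ccs", ])
    mrP <- medianRange(byRep["pvc", ])
    data.frame(density = d,
               detected_true_mm3 = median(byRep["detTrue", ]),
               ccs_median = mrC[1], ccs_min = mrC[2], ccs_max = mrC[3],
               pvc_median = mrP[1], pvc_min = mrP[2], pvc_max = mrP[3],
               row.names = NULL)
  }))
  list(perInsert = perInsert, perDensity = perDensity,
       truthVolumes = truthVols)
}
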