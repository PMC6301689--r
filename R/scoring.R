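## Per-lesion scoring: two-component Gaussian EM on the pooled
## calcification + background intensities, a threshold at the background
## mean plus half its FWHM, and linear intensity scaling of the
## supra-threshold voxels into fractional calcium content.

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Standard EM with responsibilities in the E-step and weighted moments in
#' the M-step; the log-likelihood is computed with log-sum-exp. Components
#' are relabeled so the foreground mean is the larger one. A component SD
#' falling below \code{sigmaFloor} is clamped and the fit is flagged
#' degenerate.
#'
#' @param x numeric vector of intensities (HU); at least two distinct
#'   values.
#' @param init optional list(mu = numeric(2), sigma = numeric(2),
#'   weight = numeric(2)); defaults to a quantile split.
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @param sigmaFloor SD floor in HU.
#' @return A [GaussianMixtureEstimate-class].
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 60, 15), rnorm(500, 600, 100))
#' fitTwoGaussianEM(x)
#' @export
fitTwoGaussianEM <- function(x, init = NULL, tol = 1e-6, maxIter = 200L,
                             sigmaFloor = 0.5) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two intensity values")
  if (length(unique(x)) < 2L)
    stop("all intensity values identical: mixture is undefined")
  if (is.null(init)) {
    q <- quantile(x, c(0.25, 0.75), names = FALSE)
    s <- max(sd(x) / 2, sigmaFloor)
    init <- list(mu = q, sigma = c(s, s), weight = c(0.5, 0.5))
  }
  mu <- as.numeric(init$mu)
  sig <- pmax(as.numeric(init$sigma), sigmaFloor)
  w <- as.numeric(init$weight) / sum(init$weight)
  degenerate <- FALSE
  ll <- -Inf
  converged <- FALSE
  it <- 0L
  n <- length(x)
  while (it < maxIter) {
    it <- it + 1L
    ## E-step in log space
    lp1 <- log(w[1]) + dnorm(x, mu[1], sig[1], log = TRUE)
    lp2 <- log(w[2]) + dnorm(x, mu[2], sig[2], log = TRUE)
    m <- pmax(lp1, lp2)
    lse <- m + log(exp(lp1 - m) + exp(lp2 - m))
    llNew <- sum(lse)
    r1 <- exp(lp1 - lse)
    ## M-step
    n1 <- sum(r1); n2 <- n - n1
    if (n1 < 1e-10 || n2 < 1e-10) { degenerate <- TRUE; break }
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    v1 <- sum(r1 * (x - mu[1])^2) / n1
    v2 <- sum((1 - r1) * (x - mu[2])^2) / n2
    sig <- sqrt(c(v1, v2))
    if (any(sig < sigmaFloor)) {
      degenerate <- TRUE
      sig <- pmax(sig, sigmaFloor)
    }
    w <- c(n1, n2) / n
    if (is.finite(ll) && (llNew - ll) < tol) { converged <- TRUE; ll <- llNew; break }
    ll <- llNew
  }
  ord <- order(mu)                        # background = lower mean
  ## near-collapse: component means closer than the narrower component's SD
  if (abs(mu[1] - mu[2]) < min(sig)) degenerate <- TRUE
  new("GaussianMixtureEstimate",
      muB = mu[ord[1]], sigmaB = sig[ord[1]],
      muF = mu[ord[2]], sigmaF = sig[ord[2]],
      weights = w[ord], nIterations = it, converged = converged,
      logLik = ll, degenerate = degenerate)
}

#' Per-lesion detection threshold from the background distribution
#'
#' The threshold separating a calcification from its local background is
#' the background mean plus half the background full width at half
#' maximum. For a Gaussian, FWHM = 2 sqrt(2 ln 2) sigma, so
#' threshold = muB + sqrt(2 ln 2) sigmaB.
#'
#' @param muB background mean, HU.
#' @param sigmaB background SD, HU (non-negative).
#' @return Threshold in HU.
#' @examples
#' lesionThreshold(60, 15)   # 77.66
#' @export
lesionThreshold <- function(muB, sigmaB) {
  if (any(sigmaB < 0)) stop("sigmaB must be non-negative")
  muB + sqrt(2 * log(2)) * sigmaB
}

#' Fractional calcium content of a voxel
#'
#' Linear scaling of the voxel intensity between the lesion's minimum and
#' maximum scored intensities. When the lesion has a single intensity
#' (xMax == xMin) the voxel is taken to contain calcium fully (it exceeded
#' the detection threshold), returning 1.
#'
#' @param x voxel intensity, HU.
#' @param xMin,xMax intensity scaling bounds, HU.
#' @return Fraction in [0, 1].
#' @examples
#' partialContent(200, 100, 300)  # 0.5
#' @export
partialContent <- function(x, xMin, xMax) {
  if (xMax < xMin) stop("xMax must be >= xMin")
  if (xMax == xMin) return(rep(1, length(x)))
  pmin(1, pmax(0, (x - xMin) / (xMax - xMin)))
}

#' Score one segmented lesion
#'
#' Fits the two-component mixture to the pooled calcification and
#' background intensities (initialised from the two masks' sample moments,
#' weights proportional to voxel counts), derives the per-lesion threshold
#' with [lesionThreshold()], and scores every calcification-mask voxel
#' above the threshold by its fractional calcium content. The clinical
#' volume (C-CS) is the initial voxel count times the voxel volume; the
#' corrected volume (PVC-CS) is the sum of fractions times the voxel
#' volume.
#'
#' @param volume a [CTVolume-class].
#' @param seg a [LesionSegmentation-class] from [segmentLesions()] on the
#'   same volume.
#' @param config a [RunConfig-class].
#' @return A [LesionScore-class].
#' @export
scoreLesion <- function(volume, seg, config = runConfig()) {
  hu <- intensities(volume)
  vv <- voxelVolume(volume)
  calcIdx <- calcificationIndices(seg)
  bgIdx <- backgroundIndices(seg)
  xc <- hu[calcIdx]
  xb <- hu[bgIdx]
  pooled <- c(xc, xb)

  init <- NULL
  if (length(xb) >= 2L && length(xc) >= 2L && sd(pooled) > 0)
    init <- list(mu = c(mean(xb), mean(xc)),
                 sigma = pmax(c(sd(xb), sd(xc)), config@sigmaFloor),
                 weight = c(length(xb), length(xc)))
  em <- fitTwoGaussianEM(pooled, init = init, tol = config@emTol,
                         maxIter = config@emMaxIter,
                         sigmaFloor = config@sigmaFloor)
  thr <- lesionThreshold(em@muB, em@sigmaB)

  scored <- calcIdx[hu[calcIdx] > thr]
  if (!length(scored)) {
    warning(sprintf("lesion %d: threshold %.1f HU above lesion maximum; PVC volume 0",
                    seg@labelId, thr))
    return(new("LesionScore", labelId = seg@labelId, em = em,
               thresholdHU = thr, xMin = NA_real_, xMax = NA_real_,
               scoredIdx = integer(), pvc = numeric(),
               nVoxels = length(initialIndices(seg)),
               ccsVolume = length(initialIndices(seg)) * vv, pvcVolume = 0))
  }
  xs <- hu[scored]
  xMax <- max(xs)
  xMin <- switch(config@xminMode,
                 supra_threshold = min(xs),
                 literal_lesion_min = min(xc),
                 threshold = thr)
  pvc <- partialContent(xs, xMin, xMax)
  new("LesionScore", labelId = seg@labelId, em = em, thresholdHU = thr,
      xMin = xMin, xMax = xMax, scoredIdx = as.integer(scored), pvc = pvc,
      nVoxels = length(initialIndices(seg)),
      ccsVolume = length(initialIndices(seg)) * vv,
      pvcVolume = sum(pvc) * vv)
}

#' Score a whole scan
#'
#' Detection, extension, background definition and scoring for every
#' lesion, with per-lesion error containment: a lesion whose scoring fails
#' is reported in the status vector and excluded from the totals instead
#' of aborting the scan. Deterministic given the volume and configuration.
#'
#' @param volume a [CTVolume-class].
#' @param config a [RunConfig-class].
#' @param roi optional logical array restricting detection.
#' @return A [ScanResult-class].
#' @examples
#' v <- CTVolume(array(0, c(6, 6, 3)), spacing = c(1, 1, 3))
#' ccsTotal(scoreScan(v))   # 0: nothing above 130 HU
#' @export
scoreScan <- function(volume, config = runConfig(), roi = NULL) {
  segs <- segmentLesions(volume, config, roi)
  scores <- vector("list", length(segs))
  status <- character(length(segs))
  for (i in seq_along(segs)) {
    res <- tryCatch(scoreLesion(volume, segs[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      scores[[i]] <- res
      status[i] <- "ok"
    }
  }
  ok <- !vapply(scores, is.null, TRUE)
  totals <- c(
    ccs = sum(vapply(scores[ok], function(s) s@ccsVolume, 0)),
    pvc = sum(vapply(scores[ok], function(s) s@pvcVolume, 0)))
  new("ScanResult", segmentations = segs, scores = scores, totals = totals,
      status = status, config = config)
}
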