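# Brute-force oracles, intentionally naive and independent of the
# package's compiled implementations.

# 26-connected labeling by queue-based flood fill over explicit coords.
bfLabel26 <- function(mask) {
  dims <- dim(mask)
  lab <- array(0L, dims)
  cur <- 0L
  for (st in which(mask)) {
    if (lab[st]) next
    cur <- cur + 1L
    lab[st] <- cur
    queue <- st
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      pc <- arrayInd(p, dims)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        cc <- pc + c(dx, dy, dz)
        if (any(cc < 1L) || any(cc > dims)) next
        j <- cc[1] + (cc[2] - 1L) * dims[1] + (cc[3] - 1L) * dims[1] * dims[2]
        if (mask[j] && !lab[j]) {
          lab[j] <- cur
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# As an order-independent representation: sorted list of sorted index sets.
componentsAsSets <- function(labelsOrList) {
  comps <- if (is.list(labelsOrList)) labelsOrList
  else {
    idx <- which(labelsOrList > 0L)
    unname(split(idx, labelsOrList[idx]))
  }
  comps <- lapply(comps, function(x) sort(as.integer(x)))
  comps[order(vapply(comps, min, 0L))]
}

# Exhaustive nearest-neighbor distance (mm) from every voxel to the
# nearest TRUE voxel center under anisotropic spacing.
bfDistanceToMask <- function(mask, spacing) {
  dims <- dim(mask)
  n <- prod(dims)
  tgt <- which(mask)
  if (!length(tgt)) return(array(Inf, dims))
  ac <- arrayInd(seq_len(n), dims)
  tc <- arrayInd(tgt, dims)
  d2 <- outer(ac[, 1], tc[, 1], "-")^2 * spacing[1]^2 +
    outer(ac[, 2], tc[, 2], "-")^2 * spacing[2]^2 +
    outer(ac[, 3], tc[, 3], "-")^2 * spacing[3]^2
  array(sqrt(apply(d2, 1, min)), dims)
}

randomMaskGrid <- function(dims, pTrue = 0.35) {
  array(runif(prod(dims)) < pTrue, dims)
}
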