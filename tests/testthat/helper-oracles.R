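# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity from its definition with plain R, separate from the
# package's computational path.

# Dense parallel-beam system matrix assembled row by row from the ray
# definition: detector axis (-sin a, cos a), ray direction (cos a, sin a),
# interpolated sampling across voxel-center planes of the major axis; a plane
# contributes only when both interpolation neighbors are in bounds (the
# projector's documented edge convention). Lengths in voxel units times the
# voxel size in mm.
denseParallelMatrix <- function(n, anglesDeg, ndet, pitchVox, vsMm) {
  A <- matrix(0, ndet * length(anglesDeg), n * n)
  cx <- (n - 1) / 2
  cd <- (ndet - 1) / 2
  row <- 0L
  for (a in anglesDeg * pi / 180) {
    dx <- cos(a); dy <- sin(a)
    for (j in seq_len(ndet)) {
      u <- (j - 1 - cd) * pitchVox
      qx <- cx - u * sin(a)
      qy <- cx + u * cos(a)
      w <- numeric(n * n)
      if (abs(dx) >= abs(dy)) {
        dl <- 1 / abs(dx)
        for (i in 0:(n - 1)) {
          f <- qy + (i - qx) / dx * dy
          j0 <- floor(f)
          if (j0 >= 0 && j0 + 1 <= n - 1 && f <= n - 1 - 1e-9) {
            w[i + 1 + n * j0] <- w[i + 1 + n * j0] + (1 - (f - j0)) * dl
            w[i + 1 + n * (j0 + 1)] <- w[i + 1 + n * (j0 + 1)] + (f - j0) * dl
          }
        }
      } else {
        dl <- 1 / abs(dy)
        for (i in 0:(n - 1)) {
          f <- qx + (i - qy) / dy * dx
          j0 <- floor(f)
          if (j0 >= 0 && j0 + 1 <= n - 1 && f <= n - 1 - 1e-9) {
            w[j0 + 1 + n * i] <- w[j0 + 1 + n * i] + (1 - (f - j0)) * dl
            w[j0 + 2 + n * i] <- w[j0 + 2 + n * i] + (f - j0) * dl
          }
        }
      }
      row <- row + 1L
      A[row, ] <- w * vsMm
    }
  }
  A
}

# Brute-force local thickness from the definition: a sphere centered at
# foreground voxel c has radius r_c = distance to the nearest background voxel
# center; every voxel v with |v - c| < r_c lies in that sphere and the
# reported diameter is 2 r_c - 1 voxels. Exhaustive over all centers.
bruteLocalThickness <- function(mask) {
  d <- dim(mask)
  fg <- which(mask)
  bg <- which(!mask)
  fgIdx <- arrayInd(fg, d)
  bgIdx <- arrayInd(bg, d)
  th <- array(0, dim = d)
  if (length(bg) == 0) return(th)
  for (k in seq_along(fg)) {
    c0 <- fgIdx[k, ]
    r2 <- min(colSums((t(bgIdx) - c0)^2))
    dia <- 2 * sqrt(r2) - 1
    cover <- colSums((t(fgIdx) - c0)^2) < r2
    sel <- fg[cover]
    th[sel] <- pmax(th[sel], dia)
  }
  th
}

# Exhaustive Otsu: argmax of between-class variance over all 255 cut points
# of the same 256-bin histogram.
bruteOtsu <- function(u, nBins = 256L) {
  lo <- min(u); hi <- max(u)
  w <- (hi - lo) / nBins
  bins <- pmin(floor((as.double(u) - lo) / w), nBins - 1)
  best <- -Inf
  bestK <- NA
  for (k in 0:(nBins - 2)) {
    c1 <- bins <= k
    w1 <- mean(c1)
    if (w1 == 0 || w1 == 1) next
    centers <- lo + (bins + 0.5) * w
    m1 <- mean(centers[c1]); m2 <- mean(centers[!c1])
    v <- w1 * (1 - w1) * (m1 - m2)^2
    if (v > best + 1e-15) {
      best <- v
      bestK <- k
    }
  }
  lo + (bestK + 1) * w
}

# Exact Mann-Whitney p by full enumeration of all group assignments.
bruteMannWhitney <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ranks <- rank(c(x, y))
  uOf <- function(sel) sum(ranks[sel]) - n1 * (n1 + 1) / 2
  obs <- uOf(seq_len(n1))
  sets <- utils::combn(n1 + n2, n1)
  us <- apply(sets, 2, uOf)
  mu <- n1 * n2 / 2
  pLow <- mean(us <= obs + 1e-9)
  pHigh <- mean(us >= obs - 1e-9)
  pOne <- if (obs < mu) pLow else if (obs > mu) pHigh else min(pLow, pHigh)
  list(U = obs, pOne = pOne, pTwo = min(1, 2 * min(pLow, pHigh)))
}

# Solid ball mask.
ballMask <- function(n, r, center = rep((n + 1) / 2, 3)) {
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  array(colSums((t(idx) - center)^2) <= r^2, dim = c(n, n, n))
}

# Uniform disc phantom on an n x n slice.
discPhantom <- function(n, r, value = 0.1, voxelSize = 25) {
  cx <- (n + 1) / 2
  m <- outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2)
  VoxelVolume(array(value * m, dim = c(n, n, 1L)), voxelSize)
}

discInterior <- function(n, r) {
  cx <- (n + 1) / 2
  array(outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= r^2),
        dim = c(n, n, 1L))
}

# Deterministic pseudo-random three-class phantom for DART fixtures: a disc of
# soft tissue with a few bone blobs.
threeClassPhantom <- function(n = 64L, gray = c(0, 0.038, 0.18),
                              voxelSize = 25) {
  cx <- (n + 1) / 2
  lab <- matrix(0L, n, n)
  lab[outer(1:n, 1:n, function(i, j) (i - cx)^2 + (j - cx)^2 <= (0.45 * n)^2)] <- 1L
  # overlapping blobs: the bone phase is one connected component
  blobs <- rbind(c(0.35, 0.40, 0.12), c(0.52, 0.50, 0.11),
                 c(0.45, 0.64, 0.09), c(0.60, 0.36, 0.08))
  for (b in seq_len(nrow(blobs)))
    lab[outer(1:n, 1:n, function(i, j)
      (i - blobs[b, 1] * n)^2 + (j - blobs[b, 2] * n)^2 <=
        (blobs[b, 3] * n)^2)] <- 2L
  list(volume = VoxelVolume(array(gray[lab + 1L], dim = c(n, n, 1L)),
                            voxelSize),
       labels = array(lab, dim = c(n, n, 1L)))
}
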