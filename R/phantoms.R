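#' @include AllClasses.R utils.R
NULL

# labels -> VoxelVolume with the spec's gray values
labelsToVolume <- function(labels, spec) {
  VoxelVolume(array(spec@grayValues[labels + 1L], dim = dim(labels)),
              spec@voxelSize)
}

newGroundTruth <- function(labels, morphometry, trab, plate, voxelSize) {
  bone <- labels == 2L
  morphometry$bvtv <- 100 * sum(bone & trab) / max(sum(trab), 1L)
  new("GroundTruth", labels = labels, morphometry = morphometry,
      trabecularMask = trab, plateMask = plate, voxelSize = voxelSize)
}

#' Parallel-plate phantom
#'
#' Parallel bone slabs of exact thickness separated by soft tissue, stacked
#' along the last non-singleton axis. The analytic ground truth carries
#' Tb.Th = `thickness`, Tb.S = `spacing`, and the analytic BV/TV =
#' thickness / (thickness + spacing); an oracle fixture for the thickness
#' operators.
#'
#' @param thickness slab thickness in um (at least 3 voxels).
#' @param spacing gap between slabs in um.
#' @param spec a [PhantomSpec-class] (structure "plate").
#' @return list(volume = [VoxelVolume-class], truth = [GroundTruth-class]).
#' @examples
#' spec <- PhantomSpec(c(48L, 48L, 42L), structure = "plate")
#' ph <- makePlatePhantom(225, 300, spec)
#' knownMorphometry(ph$truth)$tbth  # 225
#' @export
makePlatePhantom <- function(thickness, spacing, spec) {
  validObject(spec)
  vs <- spec@voxelSize
  if (thickness < 3 * vs)
    stop(sprintf(
      "slab thickness %.3g um is below the resolution floor of 3 voxels (%.3g um)",
      thickness, 3 * vs))
  tVox <- round(thickness / vs)
  sVox <- round(spacing / vs)
  d <- spec@gridShape
  axis <- if (d[3] > 1L) 3L else 2L
  period <- tVox + sVox
  # offset by half a gap so no slab touches the volume border (the border does
  # not count as background for the thickness operators)
  coord <- (seq_len(d[axis]) - 1L - sVox %/% 2L) %% period
  isBone <- coord < tVox
  labels <- array(1L, dim = d)
  if (axis == 3L) labels[, , isBone] <- 2L else labels[, isBone, ] <- 2L
  truth <- newGroundTruth(labels,
    list(tbth = tVox * vs, tbs = sVox * vs,
         bvtvAnalytic = 100 * thickness / (thickness + spacing),
         efReferenceSign = -1),
    maskLike(labels, TRUE), maskLike(labels, FALSE), vs)
  list(volume = labelsToVolume(labels, spec), truth = truth)
}

#' Parallel-rod phantom
#'
#' A square lattice of parallel bone cylinders along `axis`; the prolate
#' (rod-like) oracle fixture for the ellipsoid factor. Ground truth carries
#' Tb.Th = 2 * radius and the analytic BV/TV = pi r^2 / pitch^2.
#'
#' @param radius rod radius in um (at least 2 voxels).
#' @param pitch lattice pitch in um (> 2 * radius).
#' @param axis rod axis (1, 2 or 3; default 3).
#' @param spec a [PhantomSpec-class].
#' @return list(volume, truth).
#' @examples
#' spec <- PhantomSpec(c(40L, 40L, 48L), structure = "rod_lattice")
#' ph <- makeRodPhantom(100, 500, 3L, spec)
#' knownMorphometry(ph$truth)$bvtvAnalytic  # pi * 100^2 / 500^2 * 100
#' @export
makeRodPhantom <- function(radius, pitch, axis = 3L, spec) {
  validObject(spec)
  vs <- spec@voxelSize
  if (radius < 2 * vs)
    stop(sprintf("rod radius %.3g um is below 2 voxels (%.3g um)", radius,
                 2 * vs))
  if (pitch < 2 * radius)
    stop(sprintf("pitch %.3g um < 2 x radius: rods would overlap", pitch))
  d <- spec@gridShape
  rVox <- radius / vs
  pVox <- pitch / vs
  ax <- setdiff(1:3, axis)
  # rod centers at half-pitch offsets so no rod touches the volume border
  c1 <- (seq_len(d[ax[1]]) - 1 - pVox / 2) %% pVox
  c2 <- (seq_len(d[ax[2]]) - 1 - pVox / 2) %% pVox
  d1 <- pmin(c1, pVox - c1)   # distance to nearest lattice line
  d2 <- pmin(c2, pVox - c2)
  inRod2 <- outer(d1^2, d2^2, `+`) <= rVox^2
  labels <- array(1L, dim = d)
  perm <- order(c(ax, axis))
  full <- aperm(array(rep(inRod2, d[axis]),
                      dim = c(d[ax[1]], d[ax[2]], d[axis])), perm)
  labels[full] <- 2L
  truth <- newGroundTruth(labels,
    list(tbth = 2 * radius,
         bvtvAnalytic = 100 * pi * radius^2 / pitch^2,
         efReferenceSign = 1),
    maskLike(labels, TRUE), maskLike(labels, FALSE), vs)
  list(volume = labelsToVolume(labels, spec), truth = truth)
}

# Stationary zero-mean Gaussian random field with per-axis correlation
# lengths (voxel units): FFT filtering of white noise, standardized to unit
# variance. Periodic boundaries.
gaussianField <- function(d, corrVox, seed) {
  hs <- lapply(1:3, function(ax) {
    n <- d[ax]
    if (n == 1L) return(1)
    f <- c(0:floor(n / 2), seq(-(ceiling(n / 2) - 1), -1))[seq_len(n)] / n
    exp(-(pi * corrVox[ax] * f)^2)
  })
  H <- array(outer(outer(hs[[1]], hs[[2]]), hs[[3]]), dim = d)
  noise <- withSeed(seed, array(rnorm(prod(d)), dim = d))
  field <- Re(fft(fft(noise) * H, inverse = TRUE)) / prod(d)
  s <- stats::sd(field)
  if (s == 0) stop("degenerate random field")
  (field - mean(field)) / s
}

# Spherical soft-tissue pores carved into a plate mask at a target volume
# fraction. Radii ~2 voxels; deterministic under seed.
carvePores <- function(plateMask, poreFraction, seed) {
  if (poreFraction <= 0 || !any(plateMask)) return(maskLike(plateMask, FALSE))
  d <- dim(plateMask)
  idx <- which(plateMask)
  target <- poreFraction * length(idx)
  pores <- maskLike(plateMask, FALSE)
  withSeed(seed, {
    nTry <- 0L
    while (sum(pores) < target && nTry < 10000L) {
      nTry <- nTry + 1L
      c0 <- arrayInd(idx[sample.int(length(idx), 1L)], d)
      r <- runif(1, 1.2, 2.6)
      R <- ceiling(r)
      rng <- lapply(1:3, function(ax)
        max(1L, c0[ax] - R):min(d[ax], c0[ax] + R))
      box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
      keep <- rowSums((t(t(box) - as.vector(c0)))^2) <= r^2
      sel <- box[keep, , drop = FALSE]
      pores[sel] <- TRUE
    }
  })
  pores & plateMask
}

#' Stochastic trabecular phantom
#'
#' Thresholds a smooth correlated random field (zero-mean stationary Gaussian
#' field with configurable per-axis correlation lengths) at the quantile that
#' yields the target bone volume fraction inside the trabecular region, which
#' makes the achieved BV/TV deterministic up to discretization (within 0.5
#' percentage points of the target). Optionally a subchondral plate slab with
#' spherical pores is appended on one face: the +z face of a 3D grid, or the
#' +y edge of a single-slice grid. For single-slice grids the sample can be
#' confined to an inscribed disc (`structureParams$region = "disc"`),
#' surrounded by background, emulating a specimen inside the scan
#' field of view.
#'
#' structureParams fields used: `bvtv` (target percent), `corrLength` (um),
#' `anisotropy` (length-3 multipliers of the correlation length, default
#' c(1, 1, 1)), `region` ("full" or "disc"). plateLayer fields: `thickness`
#' (um), `poreFraction` (default 0.05).
#'
#' @param spec a [PhantomSpec-class] with structure "trabecular".
#' @return list(volume = [VoxelVolume-class], truth = [GroundTruth-class]).
#' @examples
#' spec <- PhantomSpec(c(48L, 48L, 48L), structure = "trabecular",
#'                     structureParams = list(bvtv = 50, corrLength = 150))
#' ph <- makeTrabecularPhantom(spec)
#' abs(knownMorphometry(ph$truth)$bvtv - 50) < 0.5
#' @export
makeTrabecularPhantom <- function(spec) {
  validObject(spec)
  if (spec@structure != "trabecular") stop("spec structure must be trabecular")
  p <- spec@structureParams
  if (is.null(p$bvtv)) stop("structureParams$bvtv (target %) is required")
  if (p$bvtv <= 0 || p$bvtv >= 100)
    stop("target BV/TV must lie strictly inside (0, 100)")
  vs <- spec@voxelSize
  d <- spec@gridShape
  corr <- if (is.null(p$corrLength)) 150 else p$corrLength
  aniso <- if (is.null(p$anisotropy)) c(1, 1, 1) else p$anisotropy
  corrVox <- corr * aniso / vs
  region <- if (is.null(p$region)) "full" else p$region

  inSample <- maskLike(array(0L, dim = d), TRUE)
  if (region == "disc") {
    cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
    rad <- 0.45 * min(d[1], d[2])
    discM <- outer(seq_len(d[1]), seq_len(d[2]),
                   function(i, j) (i - cx)^2 + (j - cy)^2 <= rad^2)
    inSample <- array(rep(discM, d[3]), dim = d)
  }

  # plate band on the +z face (3D full grid) or on a chord of the disc
  # (single slice), with a soft-tissue cap above it
  plateRegion <- maskLike(inSample, FALSE)
  softCap <- maskLike(inSample, FALSE)
  axis <- if (d[3] > 1L) 3L else 2L
  plTh <- 0L
  if (length(spec@plateLayer) > 0L && !is.null(spec@plateLayer$thickness)) {
    plTh <- max(3L, round(spec@plateLayer$thickness / vs))
    if (region == "disc" && axis == 2L) {
      # chord placement keeps the band away from the strongly curved disc cap
      yc <- (d[2] + 1) / 2 + 0.62 * 0.45 * min(d[1], d[2])
      plateIdx <- floor(yc - plTh / 2) + seq_len(plTh) - 1L
      plateIdx <- plateIdx[plateIdx >= 1L & plateIdx <= d[2]]
      capIdx <- setdiff(seq_len(d[2]), seq_len(max(plateIdx)))
    } else {
      nAx <- d[axis]
      capTh <- max(2L, round(0.3 * plTh))
      plateIdx <- (nAx - capTh - plTh + 1L):(nAx - capTh)
      capIdx <- (nAx - capTh + 1L):nAx
    }
    if (axis == 3L) {
      plateRegion[, , plateIdx] <- TRUE
      softCap[, , capIdx] <- TRUE
    } else {
      plateRegion[, plateIdx, ] <- TRUE
      softCap[, capIdx, ] <- TRUE
    }
    plateRegion <- plateRegion & inSample
    softCap <- softCap & inSample
  }

  trabRegion <- inSample & !plateRegion & !softCap

  # analysis VOI: erode the trabecular region away from sample borders
  margin <- 3
  voi <- trabRegion & erodeBall(inSample, margin)
  if (plTh > 0L) {
    away <- !dilateBall(plateRegion | softCap, margin)
    voi <- voi & away
  }
  if (!any(voi)) stop("grid too small: empty trabecular analysis region")

  field <- gaussianField(d, corrVox, spec@seed)
  # quantile threshold inside the VOI: achieved BV/TV is deterministic up to
  # discretization
  thr <- stats::quantile(field[voi], 1 - p$bvtv / 100, names = FALSE)
  labels <- array(0L, dim = d)
  labels[inSample] <- 1L
  labels[trabRegion & (field > thr)] <- 2L
  if (plTh > 0L) {
    labels[plateRegion] <- 2L
    pores <- carvePores(plateRegion, spec@plateLayer$poreFraction %||% 0.05,
                        deriveSeed(spec@seed, 17L))
    labels[pores] <- 1L
  }
  truth <- newGroundTruth(labels,
    list(plth = plTh * vs, target = p),
    voi, plateRegion, vs)
  list(volume = labelsToVolume(labels, spec), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
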