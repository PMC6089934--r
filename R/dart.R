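#' @include cgls.R
NULL

# Threshold-segment a continuous image against a GrayPrior: class 0 below
# tau1, class 1 in [tau1, tau2), class 2 above.
classifyPrior <- function(u, prior) {
  cls <- maskLike(u, 0L)
  cls[u >= prior@thresholds[1]] <- 1L
  cls[u >= prior@thresholds[2]] <- 2L
  cls
}

# Face-neighbor boundary voxels: at least one 6-neighbor with another class.
boundaryVoxels <- function(cls) {
  d <- dim(cls)
  b <- maskLike(cls, FALSE)
  shift <- function(ax, by) {
    idx <- seq_len(d[ax]) + by
    idx <- pmin(pmax(idx, 1L), d[ax])   # replicate border: no phantom class
    switch(ax, cls[idx, , , drop = FALSE], cls[, idx, , drop = FALSE],
           cls[, , idx, drop = FALSE])
  }
  for (ax in 1:3) {
    if (d[ax] == 1L) next
    for (by in c(-1L, 1L)) b <- b | (shift(ax, by) != cls)
  }
  b
}

#' DART reconstruction
#'
#' Discrete algebraic reconstruction: a CGLS initial reconstruction
#' (`dartInitIters`, default 25) is followed by `nIter` (default 25) DART
#' iterations. Each iteration threshold-segments the current image against
#' the gray-value prior, fixes interior voxels at their class gray value,
#' frees the class-boundary voxels plus a seeded random fraction
#' (1 - `dartFixProb`) of the interior, re-solves the free voxels with
#' `dartArmIters` CGLS iterations against the residual data, and blends a
#' radius-1 mean smoothing into the free voxels (weight `dartSmooth`). The
#' output is the segmented image, whose voxel values are exactly the prior's
#' gray values; set `dartContinuous` to obtain the pre-segmentation iterate.
#'
#' @param projections a [ProjectionSet-class].
#' @param operator a [TomoOperator-class] or NULL for the geometry default.
#' @param prior a [GrayPrior-class].
#' @param config a [ReconConfig-class].
#' @return A [VoxelVolume-class].
#' @export
reconstructDART <- function(projections, operator = NULL, prior,
                            config = ReconConfig("dart")) {
  validObject(prior)
  g <- geometry(projections)
  if (is.null(operator)) operator <- tomoOperator(g)
  b <- as.double(projData(projections))
  if (any(!is.finite(b))) stop("projection data contains non-finite values")
  A <- function(x) as.double(operator@forward(x))
  At <- function(y) as.double(operator@adjoint(y))
  volDim <- operator@volDim
  n <- prod(volDim)
  rho <- prior@grayValues

  init <- cglsCore(A, At, b, numeric(n), config@dartInitIters)
  u <- array(init$x, dim = volDim)

  withSeed(config@seed, {
    for (it in seq_len(config@nIter)) {
      cls <- classifyPrior(u, prior)
      seg <- array(rho[cls + 1L], dim = volDim)
      free <- boundaryVoxels(cls)
      interior <- which(!free)
      nRandom <- round((1 - config@dartFixProb) * length(interior))
      if (nRandom > 0)
        free[interior[sample.int(length(interior), nRandom)]] <- TRUE
      freeIdx <- which(free)
      if (length(freeIdx) == 0L) { u <- seg; break }

      fixedImage <- seg
      fixedImage[freeIdx] <- 0
      bRes <- b - A(as.double(fixedImage))
      embed <- function(xf) {
        full <- numeric(n)
        full[freeIdx] <- xf
        full
      }
      arm <- cglsCore(function(xf) A(embed(xf)),
                      function(y) At(y)[freeIdx],
                      bRes, u[freeIdx], config@dartArmIters)
      u <- fixedImage
      u[freeIdx] <- arm$x
      if (config@dartSmooth > 0) {
        sm <- boxFilter(u, 1L)
        u[freeIdx] <- (1 - config@dartSmooth) * u[freeIdx] +
          config@dartSmooth * sm[freeIdx]
      }
    }
  })
  if (!config@dartContinuous)
    u <- array(rho[classifyPrior(u, prior) + 1L], dim = volDim)
  VoxelVolume(u, g@voxelSize)
}

#' Contrast-to-noise ratio on the middle slice
#'
#' CNR = (mean bone ROI - mean background ROI) / SD of the background ROI,
#' evaluated on the middle slice of the volume. A constant background makes
#' the ratio undefined and returns +Inf (this happens for discrete DART
#' outputs whose background is exactly one gray value).
#'
#' @param volume a [VoxelVolume-class].
#' @param boneRoi,backgroundRoi logical arrays (full volume shape) or logical
#'   matrices on the middle slice; disjoint, each with at least 25 voxels on
#'   the middle slice.
#' @return scalar CNR (+Inf when the background SD is zero).
#' @examples
#' v <- VoxelVolume(matrix(c(rep(100, 50), rep(20, 50)), 10, 10))
#' # CNR of constant ROIs is undefined -> +Inf
#' @export
computeCNR <- function(volume, boneRoi, backgroundRoi) {
  u <- volume@data
  mid <- (dim(u)[3] + 1L) %/% 2L
  slice <- u[, , mid]
  asSlice <- function(m) {
    m <- if (length(dim(m)) == 3L) m[, , mid] else m
    if (!identical(dim(m), dim(slice))) stop("ROI shape mismatch")
    m
  }
  bone <- asSlice(boneRoi)
  bg <- asSlice(backgroundRoi)
  if (any(bone & bg)) stop("ROIs must be disjoint")
  if (sum(bone) < 25 || sum(bg) < 25)
    stop("each ROI needs at least 25 voxels on the middle slice")
  sdBg <- stats::sd(slice[bg])
  if (!is.finite(sdBg) || sdBg == 0) return(Inf)
  (mean(slice[bone]) - mean(slice[bg])) / sdBg
}
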