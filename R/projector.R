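#' @include geometry.R
NULL

# Internal: raw forward map on a plain numeric vector (voxel-unit lengths are
# converted to mm so line integrals of attenuation in 1/mm are dimensionless).
rawForward <- function(x, geom) {
  s <- geom@volShape
  vsmm <- geom@voxelSize / 1000
  angRad <- geom@angles * pi / 180
  if (geom@modality == "parallel2d") {
    p <- cpp_par2d_forward(as.double(x), s[1], s[2], angRad, geom@detCount[1],
                           geom@detPitch / geom@voxelSize)
    p * vsmm
  } else if (geom@modality == "fan2d") {
    p <- cpp_fan2d_forward(as.double(x), s[1], s[2], angRad, geom@detCount[1],
                           geom@detPitch / geom@voxelSize,
                           geom@sad * 1000 / geom@voxelSize,
                           geom@sdd * 1000 / geom@voxelSize)
    p * vsmm
  } else {
    p <- cpp_cone3d_forward(as.double(x), s[1], s[2], s[3], angRad,
                            geom@detCount[1], geom@detCount[2],
                            geom@detPitch / geom@voxelSize,
                            geom@sad * 1000 / geom@voxelSize,
                            geom@sdd * 1000 / geom@voxelSize)
    array(p * vsmm, dim = c(geom@detCount, length(geom@angles)))
  }
}

rawAdjoint <- function(y, geom) {
  s <- geom@volShape
  vsmm <- geom@voxelSize / 1000
  angRad <- geom@angles * pi / 180
  if (geom@modality == "parallel2d") {
    y <- matrix(as.double(y), geom@detCount[1], length(geom@angles))
    v <- cpp_par2d_adjoint(y, s[1], s[2], angRad, geom@detCount[1],
                           geom@detPitch / geom@voxelSize)
  } else if (geom@modality == "fan2d") {
    y <- matrix(as.double(y), geom@detCount[1], length(geom@angles))
    v <- cpp_fan2d_adjoint(y, s[1], s[2], angRad, geom@detCount[1],
                           geom@detPitch / geom@voxelSize,
                           geom@sad * 1000 / geom@voxelSize,
                           geom@sdd * 1000 / geom@voxelSize)
  } else {
    v <- cpp_cone3d_adjoint(as.double(y), s[1], s[2], s[3], angRad,
                            geom@detCount[1], geom@detCount[2],
                            geom@detPitch / geom@voxelSize,
                            geom@sad * 1000 / geom@voxelSize,
                            geom@sdd * 1000 / geom@voxelSize)
  }
  array(v * vsmm, dim = s)
}

#' Matrix-free tomographic operator for a geometry
#'
#' Wraps the ray-driven (Joseph-style interpolated sampling) forward projector
#' and its exact adjoint into a [TomoOperator-class]. Both maps are linear and
#' deterministic; the adjoint reuses the forward interpolation weights, so the
#' inner-product identity holds to floating-point accuracy.
#'
#' @param geom a [ScanGeometry-class].
#' @return A [TomoOperator-class].
#' @examples
#' g <- buildGeometry("parallel2d", nAngles = 8, stepDeg = 22.5,
#'                    lattice = c(16L, 16L, 1L))
#' A <- tomoOperator(g)
#' @export
tomoOperator <- function(geom) {
  projDim <- c(geom@detCount, length(geom@angles))
  force(geom)
  new("TomoOperator",
      forward = function(x) rawForward(x, geom),
      adjoint = function(y) rawAdjoint(y, geom),
      volDim = geom@volShape, projDim = as.integer(projDim))
}

checkLattice <- function(volume, geom) {
  if (!identical(as.integer(dim(volume)), geom@volShape) ||
      abs(voxelSize(volume) - geom@voxelSize) > 1e-9)
    stop("volume lattice does not match the geometry reference lattice")
}

#' Forward-project a volume
#'
#' Computes the line integral of attenuation along every ray of the geometry
#' (length-weighted interpolated sampling along the ray). The result is linear
#' in the volume.
#'
#' @param volume a [VoxelVolume-class] on the geometry's reference lattice.
#' @param geom a [ScanGeometry-class].
#' @return A noiseless [ProjectionSet-class].
#' @export
forwardProject <- function(volume, geom) {
  checkLattice(volume, geom)
  data <- rawForward(volume@data, geom)
  if (geom@modality != "cone3d")
    data <- array(data, dim = c(geom@detCount[1], length(geom@angles)))
  new("ProjectionSet", data = data, geometry = geom, i0 = NA_real_,
      frames = 1L)
}

#' Back-project a projection set (exact adjoint)
#'
#' The exact adjoint of [forwardProject()] -- not a filtered backprojection.
#' Needed by the least-squares solvers, whose correctness depends on true
#' adjointness.
#'
#' @param projections a [ProjectionSet-class].
#' @param geom optional geometry override; defaults to the projection set's.
#' @return A [VoxelVolume-class].
#' @export
backProject <- function(projections, geom = geometry(projections)) {
  if (!identical(dim(projData(projections)),
                 as.integer(c(geom@detCount, length(geom@angles)))))
    stop("projection data does not match the geometry")
  VoxelVolume(rawAdjoint(projData(projections), geom), geom@voxelSize)
}

#' Add Poisson photon noise with frame averaging
#'
#' For every detector element with noiseless line integral p, the transmitted
#' count has mean I0 * exp(-p); `frames` independent Poisson realizations are
#' averaged, clipped at one count to keep the logarithm finite, and re-logged
#' to a noisy line integral. Deterministic under `seed`.
#'
#' @param projections a [ProjectionSet-class].
#' @param i0 incident photon count per detector element (> 0).
#' @param frames number of frames averaged per projection (default 2).
#' @param seed random seed.
#' @return A noisy [ProjectionSet-class] carrying the noise metadata.
#' @export
addNoise <- function(projections, i0, frames = 2L, seed = 1L) {
  if (!is.finite(i0) || i0 <= 0) stop("i0 must be positive")
  frames <- as.integer(frames)
  if (frames < 1L) stop("frames must be >= 1")
  p <- projData(projections)
  noisy <- withSeed(seed, {
    mu <- rep(i0 * exp(-as.double(p)), each = frames)
    # rpois overflows 32-bit counts; the normal limit is exact to rounding
    # at such means
    counts <- ifelse(mu > 2^30,
                     round(rnorm(length(mu), mu, sqrt(mu))),
                     rpois(length(mu), pmin(mu, 2^30)))
    pmax(colMeans(matrix(counts, nrow = frames)), 1)
  })
  out <- array(log(i0) - log(noisy), dim = dim(p))
  new("ProjectionSet", data = out, geometry = geometry(projections),
      i0 = i0, frames = frames)
}

#' Keep every k-th projection view
#'
#' Subsamples the view list starting from the first view, keeping
#' ceiling(n / k) views; the geometry's angle list is updated consistently.
#' Reducing a 260-view short scan with k = 2, 4, 6 keeps 130, 65 and 44 views.
#'
#' @param projections a [ProjectionSet-class].
#' @param k positive integer subsampling factor (k = 1 returns the input).
#' @return A [ProjectionSet-class] with the reduced view set.
#' @examples
#' g <- buildGeometry("parallel2d", nAngles = 260, stepDeg = 0.7,
#'                    lattice = c(16L, 16L, 1L))
#' p <- forwardProject(VoxelVolume(array(0, c(16, 16, 1))), g)
#' length(viewAngles(subsampleProjections(p, 6)))  # 44
#' @export
subsampleProjections <- function(projections, k) {
  k <- as.integer(k)
  n <- length(viewAngles(projections))
  if (k < 1L) stop("k must be >= 1")
  if (k > n) stop(sprintf("k = %d exceeds the %d available views", k, n))
  if (k == 1L) return(projections)
  idx <- seq(1L, n, by = k)
  g <- geometry(projections)
  p <- projData(projections)
  data <- if (g@modality == "cone3d") p[, , idx, drop = FALSE]
          else p[, idx, drop = FALSE]
  new("ProjectionSet", data = data, geometry = withAngles(g, g@angles[idx]),
      i0 = projections@i0, frames = projections@frames)
}
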