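#' @include AllClasses.R accessors.R
NULL

#' Build a uniform scan geometry
#'
#' Constructs a [ScanGeometry-class] with a uniform angle list starting at
#' `startDeg` and advancing counter-clockwise by `stepDeg`, so that the
#' angular span is (nAngles - 1) * stepDeg. The short-scan micro-CT default is
#' 260 views at a 0.7 degree step (span 181.3 degrees).
#'
#' @param modality "parallel2d", "fan2d" or "cone3d".
#' @param nAngles number of views (>= 1).
#' @param stepDeg angular step in degrees (> 0).
#' @param startDeg first angle in degrees.
#' @param detCount detector element count; default sized to cover the volume
#'   shadow (length 2 for cone3d).
#' @param detPitch detector pitch in micrometres. For fan/cone this is at the
#'   detector plane; the default is voxelSize * sdd / sad so one element maps
#'   to one voxel at the isocenter.
#' @param sad,sdd source-axis / source-detector distances in mm (fan/cone).
#'   The defaults (400 / 800) give a narrow fan so that the 181.3 degree short
#'   scan covers at least 180 degrees plus the full fan angle.
#' @param lattice reference volume: a [VoxelVolume-class], or integer voxel
#'   counts (length 3).
#' @param voxelSize voxel size in um when `lattice` is given as counts.
#' @return A [ScanGeometry-class].
#' @examples
#' g <- buildGeometry("fan2d", nAngles = 260, stepDeg = 0.7,
#'                    lattice = c(256L, 256L, 1L))
#' angularSpan(g)  # 181.3
#' @export
buildGeometry <- function(modality = c("fan2d", "parallel2d", "cone3d"),
                          nAngles, stepDeg = 0.7, startDeg = 0,
                          detCount = NULL, detPitch = NULL,
                          sad = 400, sdd = 800,
                          lattice, voxelSize = 25) {
  modality <- match.arg(modality)
  stopifnot(nAngles >= 1, stepDeg > 0)
  if (is(lattice, "VoxelVolume")) {
    voxelSize <- voxelSize(lattice)
    lattice <- dim(lattice)
  }
  lattice <- as.integer(lattice)
  if (length(lattice) == 2L) lattice <- c(lattice, 1L)
  angles <- startDeg + stepDeg * seq_len(nAngles) - stepDeg
  if (modality == "parallel2d") {
    sad <- NA_real_; sdd <- NA_real_
    if (is.null(detPitch)) detPitch <- voxelSize
    if (is.null(detCount))
      detCount <- as.integer(ceiling(sqrt(2) * max(lattice[1:2])) + 2L)
  } else {
    mag <- sdd / sad
    if (is.null(detPitch)) detPitch <- voxelSize * mag
    if (is.null(detCount)) {
      n <- as.integer(ceiling(sqrt(2) * max(lattice[1:2])) + 2L)
      detCount <- if (modality == "cone3d")
        c(n, as.integer(ceiling(sqrt(2) * lattice[3]) + 2L)) else n
    }
  }
  detCount <- as.integer(detCount)
  geom <- new("ScanGeometry", modality = modality, angles = angles,
              sad = sad, sdd = sdd, detCount = detCount,
              detPitch = as.numeric(detPitch), volShape = lattice,
              voxelSize = as.numeric(voxelSize))
  shadow <- detectorShadowDeficit(geom)
  if (shadow > 0)
    warning(sprintf(
      "detector narrower than the volume shadow by %.3g mm at the isocenter",
      shadow))
  geom
}

# Positive value: how far (mm, at isocenter) the volume diagonal sticks out of
# the detector coverage.
detectorShadowDeficit <- function(geom) {
  vsmm <- geom@voxelSize / 1000
  halfDiag <- sqrt(sum((geom@volShape[1:2] * vsmm)^2)) / 2
  pitchIso <- detPitchIso(geom)
  halfDet <- (geom@detCount[1] - 1) / 2 * pitchIso
  halfDiag - halfDet
}

# Detector pitch rescaled to the isocenter (mm).
detPitchIso <- function(geom) {
  p <- geom@detPitch / 1000
  if (geom@modality == "parallel2d") p else p * geom@sad / geom@sdd
}

# Full fan angle (degrees) subtended by the detector, 0 for parallel.
fanAngleDeg <- function(geom) {
  if (geom@modality == "parallel2d") return(0)
  halfDet <- (geom@detCount[1] - 1) / 2 * detPitchIso(geom)
  2 * atan2(halfDet, geom@sad) * 180 / pi
}

# Replace the angle list (used by projection subsampling).
withAngles <- function(geom, angles) {
  new("ScanGeometry", modality = geom@modality, angles = angles,
      sad = geom@sad, sdd = geom@sdd, detCount = geom@detCount,
      detPitch = geom@detPitch, volShape = geom@volShape,
      voxelSize = geom@voxelSize)
}
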