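#' @include tomomorph-package.R
NULL

# ---- VoxelVolume ----

#' 3D scalar voxel grid
#'
#' Container for phantoms, reconstructions and filtered images: a 3D numeric
#' array on an isotropic lattice. A single-slice volume (third dimension 1)
#' represents the 2D (slice) case throughout the package. The in-memory axis
#' order is (x, y, z) column-major.
#'
#' @slot data numeric 3D array of attenuation values (1/mm).
#' @slot voxelSize isotropic voxel side length in micrometres.
#' @export
setClass("VoxelVolume",
  representation(data = "array", voxelSize = "numeric"))

setValidity("VoxelVolume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0) return("voxelSize must be a positive scalar (um)")
  TRUE
})

#' Create a VoxelVolume
#'
#' @param data numeric array (a matrix is promoted to a single-slice volume).
#' @param voxelSize isotropic voxel size in micrometres.
#' @return A [VoxelVolume-class] object.
#' @examples
#' v <- VoxelVolume(matrix(0, 8, 8), voxelSize = 25)
#' dim(v)
#' @export
VoxelVolume <- function(data, voxelSize = 25) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  new("VoxelVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' @describeIn VoxelVolume-class dimensions of the voxel grid
#' @param x a VoxelVolume
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("VoxelVolume: %d x %d x %d voxels @ %.4g um\n", d[1], d[2], d[3],
              object@voxelSize))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(object@data), max(object@data)))
})

# ---- ScanGeometry ----

#' Scan geometry
#'
#' Acquisition geometry for parallel-, fan- or cone-beam scans. Angles are in
#' degrees, strictly increasing, counter-clockwise, with the parallel ray
#' direction (cos a, sin a). The fan/cone source sits on a circle of radius
#' `sad` (source-to-axis distance); the flat detector is perpendicular to the
#' central ray at `sdd` (source-to-detector distance). Detector element 0 sits
#' at the negative transverse edge.
#'
#' @slot modality one of "parallel2d", "fan2d", "cone3d".
#' @slot angles view angles in degrees, strictly increasing.
#' @slot sad,sdd source-axis and source-detector distances (mm; NA for parallel).
#' @slot detCount detector element count (length 1, or 2 for cone3d: u, v).
#' @slot detPitch detector element pitch in micrometres (at the detector for
#'   fan/cone, at the isocenter for parallel).
#' @slot volShape reference volume lattice (voxel counts per axis).
#' @slot voxelSize reference voxel size (um).
#' @export
setClass("ScanGeometry",
  representation(modality = "character", angles = "numeric",
                 sad = "numeric", sdd = "numeric",
                 detCount = "integer", detPitch = "numeric",
                 volShape = "integer", voxelSize = "numeric"))

setValidity("ScanGeometry", function(object) {
  if (!object@modality %in% c("parallel2d", "fan2d", "cone3d"))
    return("modality must be parallel2d, fan2d or cone3d")
  if (length(object@angles) < 1L) return("need at least one angle")
  if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
    return("angles must be strictly increasing")
  if (object@modality != "parallel2d" &&
      (!is.finite(object@sad) || !is.finite(object@sdd) ||
       object@sad <= 0 || object@sdd <= 0))
    return("fan/cone geometries need positive sad and sdd (mm)")
  nd <- if (object@modality == "cone3d") 2L else 1L
  if (length(object@detCount) != nd || any(object@detCount < 1L))
    return("bad detector element count")
  if (object@detPitch <= 0) return("detector pitch must be positive (um)")
  if (length(object@volShape) != 3L || any(object@volShape < 1L))
    return("volShape must be three positive voxel counts")
  if (object@voxelSize <= 0) return("voxelSize must be positive (um)")
  TRUE
})

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %s, %d views over %.4g deg\n", object@modality,
              length(object@angles), angularSpan(object)))
  cat(sprintf("  detector %s elements @ %.4g um; lattice %s @ %.4g um\n",
              paste(object@detCount, collapse = " x "), object@detPitch,
              paste(object@volShape, collapse = " x "), object@voxelSize))
  if (object@modality != "parallel2d")
    cat(sprintf("  sad %.4g mm, sdd %.4g mm\n", object@sad, object@sdd))
})

# ---- ProjectionSet ----

#' Projection data (sinogram)
#'
#' Per-angle detector readings (line integrals of attenuation, dimensionless)
#' together with the scan geometry and the photon-noise metadata. The data
#' array is (detector, angle) for 2D modalities and (u, v, angle) for cone3d.
#'
#' @slot data numeric array of line integrals.
#' @slot geometry the [ScanGeometry-class].
#' @slot i0 incident photon count per detector element (NA when noiseless).
#' @slot frames number of frames averaged per projection.
#' @export
setClass("ProjectionSet",
  representation(data = "array", geometry = "ScanGeometry",
                 i0 = "numeric", frames = "integer"))

setValidity("ProjectionSet", function(object) {
  g <- object@geometry
  want <- c(g@detCount, length(g@angles))
  if (!identical(as.integer(dim(object@data)), as.integer(want)))
    return(sprintf("data dim (%s) does not match geometry (%s)",
                   paste(dim(object@data), collapse = ","),
                   paste(want, collapse = ",")))
  if (!all(is.finite(object@data))) return("projection data must be finite")
  TRUE
})

setMethod("show", "ProjectionSet", function(object) {
  cat(sprintf("ProjectionSet: %d views (%s), %s\n",
              length(object@geometry@angles), object@geometry@modality,
              if (is.na(object@i0)) "noiseless"
              else sprintf("Poisson noise I0 = %.3g, %d frame(s)",
                           object@i0, object@frames)))
})

# ---- TomoOperator ----

#' Matrix-free tomographic operator
#'
#' A linear forward map A (volume to projections) and its exact adjoint
#' (projections to volume), both deterministic and matrix-free. The pair
#' satisfies the inner-product identity <A x, y> = <x, A' y> by construction
#' because the adjoint reuses the forward traversal weights.
#'
#' @slot forward function(numeric vector of length prod(volDim)) -> projections.
#' @slot adjoint function(projection vector) -> volume vector.
#' @slot volDim voxel counts of the volume lattice.
#' @slot projDim dimensions of the projection array.
#' @export
setClass("TomoOperator",
  representation(forward = "function", adjoint = "function",
                 volDim = "integer", projDim = "integer"))

setMethod("show", "TomoOperator", function(object) {
  cat(sprintf("TomoOperator: volume %s -> projections %s\n",
              paste(object@volDim, collapse = "x"),
              paste(object@projDim, collapse = "x")))
})

# ---- GrayPrior ----

#' Discrete gray-value prior for DART
#'
#' Ordered admissible gray values (background, soft tissue, bone) and the two
#' segmentation thresholds between them: rho0 < tau1 < rho1 < tau2 < rho2.
#'
#' @slot grayValues the three admissible attenuation values (1/mm).
#' @slot thresholds the two class thresholds.
#' @export
setClass("GrayPrior",
  representation(grayValues = "numeric", thresholds = "numeric"))

setValidity("GrayPrior", function(object) {
  g <- object@grayValues; t <- object@thresholds
  if (length(g) != 3L || length(t) != 2L)
    return("need three gray values and two thresholds")
  ok <- g[1] < t[1] && t[1] < g[2] && g[2] < t[2] && t[2] < g[3]
  if (!ok) return("ordering rho0 < tau1 < rho1 < tau2 < rho2 violated")
  TRUE
})

#' Create a gray-value prior
#'
#' @param grayValues ordered triple (background, soft tissue, bone), 1/mm.
#' @param thresholds two class thresholds; default midpoints between the
#'   gray values.
#' @return A [GrayPrior-class].
#' @examples
#' GrayPrior(c(0, 0.038, 0.18))
#' @export
GrayPrior <- function(grayValues,
                      thresholds = (grayValues[-3] + grayValues[-1]) / 2) {
  new("GrayPrior", grayValues = as.numeric(grayValues),
      thresholds = as.numeric(thresholds))
}

# ---- PhantomSpec ----

#' Phantom specification
#'
#' Parameters of a synthetic three-material phantom. `structureParams` holds
#' structure-specific settings in micrometres / percent: thickness, spacing,
#' radius, pitch, target bone volume fraction (`bvtv`), correlation length
#' (`corrLength`), per-axis anisotropy multipliers (`anisotropy`).
#'
#' @slot gridShape voxel counts per axis.
#' @slot voxelSize isotropic voxel size (um).
#' @slot grayValues attenuation triple (background, soft tissue, bone), 1/mm.
#' @slot structure one of "plate", "rod_lattice", "sphere", "trabecular".
#' @slot structureParams named list of structure parameters.
#' @slot plateLayer optional subchondral plate: list(thickness, poreFraction)
#'   (um, fraction); empty list for none.
#' @slot seed integer random seed.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSize = "numeric",
                 grayValues = "numeric", structure = "character",
                 structureParams = "list", plateLayer = "list",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@gridShape < 1L)) return("gridShape must be positive")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  if (length(object@grayValues) != 3L || any(diff(object@grayValues) <= 0))
    return("grayValues must be a strictly increasing triple")
  if (!object@structure %in% c("plate", "rod_lattice", "sphere", "trabecular"))
    return("unknown structure")
  bv <- object@structureParams$bvtv
  if (!is.null(bv) && (bv <= 0 || bv >= 100))
    return("target BV/TV must lie in (0, 100)")
  TRUE
})

#' Create a phantom specification
#'
#' @param gridShape voxel counts per axis (length 2 treated as a single slice).
#' @param voxelSize isotropic voxel size, um.
#' @param grayValues attenuation triple (background, soft tissue, bone), 1/mm.
#' @param structure structure family.
#' @param structureParams named list, see [PhantomSpec-class].
#' @param plateLayer optional list(thickness, poreFraction).
#' @param seed random seed.
#' @return A [PhantomSpec-class].
#' @export
PhantomSpec <- function(gridShape, voxelSize = 25,
                        grayValues = c(0, 0.038, 0.18),
                        structure = "trabecular",
                        structureParams = list(), plateLayer = list(),
                        seed = 1L) {
  if (length(gridShape) == 2L) gridShape <- c(gridShape, 1L)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSize = as.numeric(voxelSize), grayValues = as.numeric(grayValues),
      structure = structure, structureParams = structureParams,
      plateLayer = plateLayer, seed = as.integer(seed))
}

# ---- GroundTruth ----

#' Ground truth of a synthetic phantom
#'
#' Per-voxel class labels (0 background, 1 soft tissue, 2 bone), the known
#' morphometry of the construction, and the analysis region masks that stand
#' in for manual delineation of trabecular and plate compartments.
#'
#' @slot labels integer array of class labels.
#' @slot morphometry named list of known values; always contains `bvtv`
#'   recomputed exactly from the labels within the trabecular region; analytic
#'   constructions add `tbth`, `tbs`, `bvtvAnalytic` etc.
#' @slot trabecularMask logical array: the trabecular analysis VOI.
#' @slot plateMask logical array: the subchondral plate region.
#' @slot voxelSize voxel size (um).
#' @export
setClass("GroundTruth",
  representation(labels = "array", morphometry = "list",
                 trabecularMask = "array", plateMask = "array",
                 voxelSize = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %s voxels, BV/TV %.2f%%\n",
              paste(dim(object@labels), collapse = "x"),
              object@morphometry$bvtv))
})

# ---- CohortSpec ----

#' Cohort specification
#'
#' A synthetic study group: number of samples and per-parameter calibration
#' targets (mean and SD) for BV/TV (%), Tb.Th (um), Tb.S (um) and Pl.Th (um).
#'
#' @slot group group label ("aclt" or "control").
#' @slot n number of samples.
#' @slot targets named list of c(mean, sd) per parameter.
#' @slot baseSeed base random seed.
#' @slot mode "voi3d" (3D volume of interest) or "slice2d" (single fan-beam
#'   slice with an embedded plate band).
#' @slot gridShape voxel counts of each phantom.
#' @export
setClass("CohortSpec",
  representation(group = "character", n = "integer", targets = "list",
                 baseSeed = "integer", mode = "character",
                 gridShape = "integer"))

setValidity("CohortSpec", function(object) {
  if (object@n < 1L) return("n must be >= 1")
  for (p in c("bvtv", "tbth", "tbs", "plth")) {
    t <- object@targets[[p]]
    if (is.null(t) || length(t) != 2L || t[2] < 0)
      return(sprintf("target %s must be c(mean, sd) with sd >= 0", p))
  }
  if (!object@mode %in% c("voi3d", "slice2d")) return("unknown mode")
  TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %s, n = %d (%s)\n", object@group, object@n,
              object@mode))
  for (p in names(object@targets))
    cat(sprintf("  %s: %.4g +/- %.4g\n", p, object@targets[[p]][1],
                object@targets[[p]][2]))
})

# ---- MorphometryResult ----

#' Morphometric parameters of one sample
#'
#' The six direct-3D structural parameters of subchondral bone.
#'
#' @slot bvtv bone volume fraction, percent.
#' @slot tbth mean trabecular thickness, um.
#' @slot tbs mean trabecular separation, um.
#' @slot tbn trabecular number, 1/mm.
#' @slot ef ellipsoid factor, unitless in [-1, 1].
#' @slot plth subchondral plate thickness, um.
#' @export
setClass("MorphometryResult",
  representation(bvtv = "numeric", tbth = "numeric", tbs = "numeric",
                 tbn = "numeric", ef = "numeric", plth = "numeric"))

setValidity("MorphometryResult", function(object) {
  if (object@bvtv < 0 || object@bvtv > 100) return("BV/TV outside [0, 100]")
  if (any(c(object@tbth, object@tbs, object@plth) < 0, na.rm = TRUE))
    return("thicknesses must be >= 0")
  if (!is.na(object@ef) && (object@ef < -1 || object@ef > 1))
    return("EF outside [-1, 1]")
  TRUE
})

setMethod("show", "MorphometryResult", function(object) {
  cat(sprintf(paste0("MorphometryResult: BV/TV %.2f%%, Tb.Th %.1f um, ",
                     "Tb.S %.1f um, Tb.N %.3f 1/mm, EF %.3f, Pl.Th %.1f um\n"),
              object@bvtv, object@tbth, object@tbs, object@tbn, object@ef,
              object@plth))
})

#' @describeIn MorphometryResult-class one-row data frame of the six parameters
#' @param x a MorphometryResult
#' @param row.names,optional,... ignored
#' @export
setMethod("as.data.frame", "MorphometryResult",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(bvtv = x@bvtv, tbth = x@tbth, tbs = x@tbs, tbn = x@tbn,
               ef = x@ef, plth = x@plth)
  })

# ---- ReconConfig ----

#' Reconstruction configuration
#'
#' Algorithm selection and constants for the reconstruction module. Defaults:
#' 25 base iterations for every method, Hamming window alpha 0.54, DART with a
#' 25-iteration CGLS initial reconstruction and 10 CGLS iterations per
#' algebraic step, fix probability 0.99 and smoothing blend 0.1.
#'
#' @slot algorithm "fdk", "cgls", "tv" or "dart".
#' @slot nIter base iteration count.
#' @slot hammingAlpha Hamming window parameter in [0.5, 1].
#' @slot tvLambda TV regularization weight (>= 0).
#' @slot tvEpsilon gradient-smoothing constant (NA: 1e-4 x data-derived scale).
#' @slot dartArmIters CGLS iterations per DART algebraic step.
#' @slot dartInitIters CGLS iterations for the DART initial reconstruction.
#' @slot dartFixProb probability of fixing a non-boundary voxel.
#' @slot dartSmooth blending weight of the radius-1 mean smoothing.
#' @slot dartContinuous return the continuous iterate instead of the
#'   segmented image.
#' @slot seed random seed (DART free-voxel sampling).
#' @export
setClass("ReconConfig",
  representation(algorithm = "character", nIter = "integer",
                 hammingAlpha = "numeric", tvLambda = "numeric",
                 tvEpsilon = "numeric", dartArmIters = "integer",
                 dartInitIters = "integer", dartFixProb = "numeric",
                 dartSmooth = "numeric", dartContinuous = "logical",
                 seed = "integer"))

setValidity("ReconConfig", function(object) {
  if (!object@algorithm %in% c("fdk", "cgls", "tv", "dart"))
    return("unknown algorithm")
  if (object@nIter < 1L) return("nIter must be >= 1")
  if (object@hammingAlpha < 0.5 || object@hammingAlpha > 1)
    return("hammingAlpha must lie in [0.5, 1]")
  if (object@tvLambda < 0) return("tvLambda must be >= 0")
  if (object@dartFixProb < 0 || object@dartFixProb > 1)
    return("dartFixProb must lie in [0, 1]")
  TRUE
})

#' Create a reconstruction configuration
#'
#' @param algorithm algorithm id.
#' @param nIter base iterations (default 25).
#' @param hammingAlpha Hamming window parameter (default 0.54).
#' @param tvLambda,tvEpsilon TV weight and gradient smoothing.
#' @param dartArmIters,dartInitIters,dartFixProb,dartSmooth,dartContinuous
#'   DART constants, see [ReconConfig-class].
#' @param seed random seed.
#' @return A [ReconConfig-class].
#' @export
ReconConfig <- function(algorithm = "cgls", nIter = 25L, hammingAlpha = 0.54,
                        tvLambda = 0, tvEpsilon = NA_real_,
                        dartArmIters = 10L, dartInitIters = 25L,
                        dartFixProb = 0.99, dartSmooth = 0.1,
                        dartContinuous = FALSE, seed = 1L) {
  new("ReconConfig", algorithm = algorithm, nIter = as.integer(nIter),
      hammingAlpha = hammingAlpha, tvLambda = tvLambda, tvEpsilon = tvEpsilon,
      dartArmIters = as.integer(dartArmIters),
      dartInitIters = as.integer(dartInitIters), dartFixProb = dartFixProb,
      dartSmooth = dartSmooth, dartContinuous = dartContinuous,
      seed = as.integer(seed))
}

# ---- SegmentationConfig ----

#' Segmentation configuration
#'
#' Constants of the bone segmentation chain: median filter radius 1, unsharp
#' mask radius 1 at 50 percent amount, 26-connectivity despeckling, and a
#' 2-voxel closing for plate cleanup.
#'
#' @slot medianRadius cubic median filter radius (voxels).
#' @slot unsharpRadius unsharp mask blur radius (voxels).
#' @slot unsharpAmount unsharp amount in percent.
#' @slot connectivity component connectivity, 6 or 26.
#' @slot closingRadius ball radius of the plate morphological closing.
#' @slot despeckleMode "keep-largest" (the 3D sweep; default) or "min-size"
#'   (drop components below `minSpeckleSize` voxels -- appropriate for
#'   single-slice data, where a connected 3D network fragments in
#'   cross-section and a keep-largest sweep would discard real bone).
#' @slot minSpeckleSize smallest component kept by the "min-size" mode.
#' @export
setClass("SegmentationConfig",
  representation(medianRadius = "integer", unsharpRadius = "integer",
                 unsharpAmount = "numeric", connectivity = "integer",
                 closingRadius = "integer", despeckleMode = "character",
                 minSpeckleSize = "integer"))

setValidity("SegmentationConfig", function(object) {
  if (object@medianRadius < 0L || object@unsharpRadius < 0L ||
      object@closingRadius < 0L) return("radii must be >= 0")
  if (object@unsharpAmount < 0) return("unsharp amount must be >= 0")
  if (!object@connectivity %in% c(6L, 26L)) return("connectivity must be 6 or 26")
  if (!object@despeckleMode %in% c("keep-largest", "min-size"))
    return("despeckleMode must be keep-largest or min-size")
  TRUE
})

#' Create a segmentation configuration
#'
#' @param medianRadius,unsharpRadius,unsharpAmount,connectivity,closingRadius
#'   see [SegmentationConfig-class].
#' @param despeckleMode,minSpeckleSize despeckling behavior, see
#'   [SegmentationConfig-class].
#' @return A [SegmentationConfig-class].
#' @export
SegmentationConfig <- function(medianRadius = 1L, unsharpRadius = 1L,
                               unsharpAmount = 50, connectivity = 26L,
                               closingRadius = 2L,
                               despeckleMode = "keep-largest",
                               minSpeckleSize = 30L) {
  new("SegmentationConfig", medianRadius = as.integer(medianRadius),
      unsharpRadius = as.integer(unsharpRadius),
      unsharpAmount = unsharpAmount, connectivity = as.integer(connectivity),
      closingRadius = as.integer(closingRadius), despeckleMode = despeckleMode,
      minSpeckleSize = as.integer(minSpeckleSize))
}

# ---- TestResult ----

#' Exact Mann-Whitney test result
#'
#' @slot U the Mann-Whitney U statistic of the first group (midrank ties).
#' @slot pOne one-tailed exact p for the observed direction.
#' @slot pTwo two-tailed exact p.
#' @slot n1,n2 group sizes.
#' @export
setClass("TestResult",
  representation(U = "numeric", pOne = "numeric", pTwo = "numeric",
                 n1 = "integer", n2 = "integer"))

setValidity("TestResult", function(object) {
  if (object@U < 0 || object@U > object@n1 * object@n2)
    return("U outside [0, n1*n2]")
  if (object@pOne <= 0 || object@pOne > 1 || object@pTwo <= 0 ||
      object@pTwo > 1) return("p-values must lie in (0, 1]")
  TRUE
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("Mann-Whitney exact: U = %.1f (n = %d, %d), p = %.4g (%.4g)\n",
              object@U, object@n1, object@n2, object@pOne, object@pTwo))
})
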