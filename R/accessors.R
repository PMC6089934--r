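#' @include AllClasses.R
NULL

#' Voxel data of a volume
#' @param object a [VoxelVolume-class] or [GroundTruth-class]
#' @return the underlying array
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' @rdname voxelData
#' @export
setMethod("voxelData", "VoxelVolume", function(object) object@data)

#' Isotropic voxel size in micrometres
#' @param object an object carrying a voxel lattice
#' @return voxel size (um)
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VoxelVolume", function(object) object@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "ScanGeometry", function(object) object@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "GroundTruth", function(object) object@voxelSize)

#' Projection data array
#' @param object a [ProjectionSet-class]
#' @return the (detector x angle) or (u x v x angle) array of line integrals
#' @export
setGeneric("projData", function(object) standardGeneric("projData"))

#' @rdname projData
#' @export
setMethod("projData", "ProjectionSet", function(object) object@data)

#' Scan geometry of a projection set
#' @param object a [ProjectionSet-class]
#' @return the [ScanGeometry-class]
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname geometry
#' @export
setMethod("geometry", "ProjectionSet", function(object) object@geometry)

#' View angles in degrees
#' @param object a [ScanGeometry-class] or [ProjectionSet-class]
#' @return numeric vector of angles (degrees)
#' @export
setGeneric("viewAngles", function(object) standardGeneric("viewAngles"))

#' @rdname viewAngles
#' @export
setMethod("viewAngles", "ScanGeometry", function(object) object@angles)

#' @rdname viewAngles
#' @export
setMethod("viewAngles", "ProjectionSet", function(object) object@geometry@angles)

#' Angular span of a geometry in degrees
#'
#' The span is last angle minus first angle; for a uniform geometry with
#' n views and step s this equals (n - 1) * s (260 views at 0.7 degrees span
#' 181.3 degrees).
#'
#' @param object a [ScanGeometry-class] or [ProjectionSet-class]
#' @return span in degrees (0 for a single view)
#' @examples
#' g <- buildGeometry("parallel2d", nAngles = 260, stepDeg = 0.7,
#'                    lattice = c(32L, 32L, 1L))
#' angularSpan(g)  # 181.3
#' @export
setGeneric("angularSpan", function(object) standardGeneric("angularSpan"))

#' @rdname angularSpan
#' @export
setMethod("angularSpan", "ScanGeometry",
          function(object) diff(range(object@angles)))

#' @rdname angularSpan
#' @export
setMethod("angularSpan", "ProjectionSet",
          function(object) angularSpan(object@geometry))

#' Ground-truth class labels
#' @param object a [GroundTruth-class]
#' @return integer array (0 background, 1 soft tissue, 2 bone)
#' @export
setGeneric("phantomLabels", function(object) standardGeneric("phantomLabels"))

#' @rdname phantomLabels
#' @export
setMethod("phantomLabels", "GroundTruth", function(object) object@labels)

#' Region masks of a ground truth
#' @param object a [GroundTruth-class]
#' @return list(trabecular = , plate = ) of logical arrays
#' @export
setGeneric("regionMasks", function(object) standardGeneric("regionMasks"))

#' @rdname regionMasks
#' @export
setMethod("regionMasks", "GroundTruth", function(object)
  list(trabecular = object@trabecularMask, plate = object@plateMask))

#' Known morphometry of a ground truth
#' @param object a [GroundTruth-class]
#' @return named list; always contains `bvtv` (exact, from labels)
#' @export
setGeneric("knownMorphometry",
           function(object) standardGeneric("knownMorphometry"))

#' @rdname knownMorphometry
#' @export
setMethod("knownMorphometry", "GroundTruth", function(object) object@morphometry)
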