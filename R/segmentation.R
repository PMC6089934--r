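#' @include AllClasses.R utils.R
NULL

#' Pre-threshold filtering
#'
#' The image-processing front of the segmentation chain: a cubic median
#' filter (radius `medianRadius`) followed by an unsharp mask
#' v + (amount/100) * (v - blur(v)) whose blur is a mean filter of radius
#' `unsharpRadius`. A constant volume is a fixed point of both stages.
#'
#' @param volume a [VoxelVolume-class] or numeric array.
#' @param config a [SegmentationConfig-class].
#' @return same type as the input.
#' @export
prefilterVolume <- function(volume, config = SegmentationConfig()) {
  isVol <- is(volume, "VoxelVolume")
  u <- if (isVol) volume@data else as3d(volume)
  if (config@medianRadius > 0L) u <- medianFilter3(u, config@medianRadius)
  if (config@unsharpRadius > 0L && config@unsharpAmount > 0)
    u <- u + (config@unsharpAmount / 100) * (u - boxFilter(u, config@unsharpRadius))
  if (isVol) VoxelVolume(u, volume@voxelSize) else u
}

#' Global Otsu threshold of a 3D volume
#'
#' Maximizes the between-class variance over a 256-bin histogram of the full
#' volume (bins half-open over [min, max]); deterministic, ties resolve to
#' the lowest threshold. Binarize with `volume >= threshold`. The threshold
#' is equivariant under affine intensity rescaling up to bin mapping.
#'
#' @param volume a [VoxelVolume-class] or numeric array with at least two
#'   distinct values.
#' @param nBins histogram bins (default 256).
#' @return the threshold value (lower edge of the first foreground bin).
#' @export
otsuThreshold <- function(volume, nBins = 256L) {
  u <- if (is(volume, "VoxelVolume")) volume@data else volume
  lo <- min(u); hi <- max(u)
  if (lo == hi) stop("constant volume: Otsu threshold undefined")
  w <- (hi - lo) / nBins
  bins <- pmin(floor((as.double(u) - lo) / w), nBins - 1)  # half-open bins
  counts <- tabulate(bins + 1L, nbins = nBins)
  p <- counts / sum(counts)
  centers <- lo + (seq_len(nBins) - 0.5) * w
  omega <- cumsum(p)
  mu <- cumsum(p * centers)
  muT <- mu[nBins]
  # cut after bin k: classes [1..k] vs [k+1..nBins]
  k <- seq_len(nBins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigmaB <- ifelse(denom > 0, (muT * omega[k] - mu[k])^2 / denom, -Inf)
  best <- which(sigmaB == max(sigmaB))[1]   # ties -> lowest threshold
  lo + best * w
}

#' Keep the largest connected component
#'
#' The despeckling sweep: retains only the largest connected foreground
#' component (connectivity 6 or 26). On a tie the component containing the
#' first voxel in lexicographic scan order is kept.
#'
#' @param mask non-empty logical array.
#' @param connectivity 6 or 26 (default 26).
#' @return logical array with a single component.
#' @export
despeckleKeepLargest <- function(mask, connectivity = 26L) {
  mask <- as3d(mask)
  if (!any(mask)) stop("empty mask")
  lab <- labelComponents(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes == max(sizes))[1]   # labels follow scan order: tie rule
  array(lab == keep, dim = dim(mask))
}

#' Clean a plate mask
#'
#' Fills interior pores (background components not connected to the volume
#' border become foreground) and then applies morphological closing with a
#' Euclidean ball of `closingRadius` voxels to remove pores at the plate
#' edges.
#'
#' @param mask logical plate mask.
#' @param config a [SegmentationConfig-class].
#' @return cleaned logical array.
#' @export
cleanPlate <- function(mask, config = SegmentationConfig()) {
  mask <- as3d(mask)
  d <- dim(mask)
  # background uses the complementary 6-connectivity so diagonal leaks do not
  # connect interior pores to the outside
  lab <- labelComponents(!mask, 6L)
  border <- maskLike(mask, FALSE)
  border[c(1L, d[1]), , ] <- TRUE
  border[, c(1L, d[2]), ] <- TRUE
  if (d[3] > 1L) border[, , c(1L, d[3])] <- TRUE
  borderLabels <- unique(lab[border & !mask])
  interiorPore <- !mask & !(lab %in% borderLabels)
  filled <- mask | array(interiorPore, dim = d)
  if (config@closingRadius > 0L) {
    # close in a background-padded domain so structures touching the volume
    # border are not artificially closed against it
    r <- config@closingRadius
    zr <- if (d[3] > 1L) r else 0L
    dp <- c(d[1] + 2L * r, d[2] + 2L * r, d[3] + 2L * zr)
    pad <- array(FALSE, dim = dp)
    pad[r + seq_len(d[1]), r + seq_len(d[2]), zr + seq_len(d[3])] <- filled
    closed <- erodeBall(dilateBall(pad, r), r)
    filled <- closed[r + seq_len(d[1]), r + seq_len(d[2]), zr + seq_len(d[3]),
                     drop = FALSE]
  }
  array(filled, dim = d)
}

#' Remove small components
#'
#' Min-size despeckling: drops connected foreground components smaller than
#' `minSize` voxels. The variant used for single-slice data, where the
#' keep-largest sweep would discard genuine bone cross-sections.
#'
#' @param mask logical array.
#' @param minSize smallest component kept (voxels).
#' @param connectivity 6 or 26.
#' @return logical array.
#' @export
despeckleMinSize <- function(mask, minSize = 30L, connectivity = 26L) {
  mask <- as3d(mask)
  if (!any(mask)) return(mask)
  lab <- labelComponents(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minSize)
  array(lab %in% keep, dim = dim(mask))
}

#' Bone segmentation chain
#'
#' From a reconstructed grayscale volume to analysis-ready binary masks:
#' prefilter (median + unsharp), global 3D Otsu threshold, despeckling
#' (keep-largest sweep by default; the min-size mode for single-slice data),
#' then restriction to the trabecular and plate regions; the plate mask is
#' additionally pore-filled and closed with [cleanPlate()].
#'
#' @param volume a [VoxelVolume-class].
#' @param regions list(trabecular = , plate = ) of logical region masks (from
#'   the phantom ground truth, or user-drawn for external data); both must be
#'   non-empty unless the phantom has no plate (all-FALSE plate is allowed and
#'   yields an all-FALSE plate mask).
#' @param config a [SegmentationConfig-class].
#' @return list(trabecular = , plate = ) of logical masks.
#' @export
segmentBone <- function(volume, regions, config = SegmentationConfig()) {
  if (is.null(regions$trabecular) || sum(regions$trabecular) == 0)
    stop("empty trabecular region mask")
  filt <- prefilterVolume(volume, config)
  thr <- otsuThreshold(filt)
  bone <- as3d(voxelData(filt) >= thr)
  bone <- if (config@despeckleMode == "keep-largest")
    despeckleKeepLargest(bone, config@connectivity)
  else despeckleMinSize(bone, config@minSpeckleSize, config@connectivity)
  trab <- bone & as3d(regions$trabecular)
  plate <- if (!is.null(regions$plate) && any(regions$plate))
    cleanPlate(bone & as3d(regions$plate), config)
  else maskLike(bone, FALSE)
  list(trabecular = trab, plate = plate)
}
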