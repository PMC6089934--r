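#' @include AllClasses.R geometry.R
NULL

sidecarPath <- function(path) paste0(path, ".json")

#' Read / write voxel volumes
#'
#' Volumes are stored as multi-page TIFF stacks (one page per z slice, rows =
#' y, columns = x) or as NIfTI (64-bit float, voxel size in the header, mm).
#' TIFF payloads are 8- or 16-bit unsigned integers (masks, labels, count
#' data; integer values round-trip bitwise) or 32-bit floats rescaled to the
#' recorded [min, max] range (grayscale data; round trips are exact at 32-bit
#' float precision). TIFF has no voxel-size tag, so a JSON sidecar
#' `<path>.json` carrying `voxel_size_um` and the intensity scaling is
#' written alongside and is mandatory on read -- a missing voxel size is an
#' error, not a silent default.
#'
#' @param volume a [VoxelVolume-class].
#' @param path file path; format chosen by extension (.tif/.tiff or
#'   .nii/.nii.gz).
#' @param type "float32" (default), "uint8" (values 0..255) or "uint16"
#'   (values 0..65535).
#' @return `writeVolume` returns the path invisibly; `readVolume` returns a
#'   [VoxelVolume-class].
#' @export
writeVolume <- function(volume, path, type = c("float32", "uint8", "uint16")) {
  type <- match.arg(type)
  u <- volume@data
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(u)
    img <- RNifti::`pixdim<-`(img, rep(volume@voxelSize / 1000, 3))
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  meta <- list(voxel_size_um = volume@voxelSize, type = type,
               axis_order = "z,y,x")
  pages <- lapply(seq_len(dim(u)[3]), function(k) t(u[, , k]))
  if (type == "uint8") {
    tiff::writeTIFF(lapply(pages, function(m) m / 255), path,
                    bits.per.sample = 8L)
  } else if (type == "uint16") {
    tiff::writeTIFF(lapply(pages, function(m) m / 65535), path,
                    bits.per.sample = 16L)
  } else {
    lo <- min(u); hi <- max(u)
    scale <- if (hi > lo) hi - lo else 1
    meta$offset <- lo
    meta$scale <- scale
    tiff::writeTIFF(lapply(pages, function(m) (m - lo) / scale), path,
                    bits.per.sample = 32L)
  }
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    vs <- RNifti::pixdim(img)[1] * 1000
    return(VoxelVolume(array(as.numeric(img), dim = dim(img)), vs))
  }
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    stop("missing voxel-size sidecar ", sc,
         ": voxel size must be stated explicitly")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$voxel_size_um)) stop("sidecar lacks voxel_size_um")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  arr <- switch(meta$type,
                uint8 = round(arr * 255),
                uint16 = round(arr * 65535),
                arr * (meta$scale %||% 1) + (meta$offset %||% 0))
  VoxelVolume(arr, meta$voxel_size_um)
}

#' Read / write sinograms
#'
#' Sinograms are stored as a plain-text matrix (one line per view; values in
#' full "%.17g" precision, so round trips are bit-exact) plus a mandatory
#' JSON geometry sidecar `<path>.json` holding the modality, angles,
#' distances, detector layout, reference lattice and noise metadata. A
#' missing or inconsistent sidecar is an error.
#'
#' @param projections a [ProjectionSet-class].
#' @param path data file path (e.g. "sino.txt").
#' @return `writeSinogram` returns the path invisibly; `readSinogram` a
#'   [ProjectionSet-class].
#' @export
writeSinogram <- function(projections, path) {
  g <- geometry(projections)
  p <- projData(projections)
  mat <- if (g@modality == "cone3d")
    matrix(as.double(p), prod(g@detCount), length(g@angles))
  else p
  lines <- apply(mat, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ","))
  writeLines(lines, path)
  jsonlite::write_json(list(
    modality = g@modality, angles_deg = g@angles, sad_mm = g@sad,
    sdd_mm = g@sdd, det_count = g@detCount, det_pitch_um = g@detPitch,
    vol_shape = g@volShape, voxel_size_um = g@voxelSize,
    i0 = projections@i0, frames = projections@frames),
    sidecarPath(path), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeSinogram
#' @export
readSinogram <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) stop("missing geometry sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("modality", "angles_deg", "det_count", "det_pitch_um",
            "vol_shape", "voxel_size_um")
  miss <- need[!need %in% names(meta)]
  if (length(miss))
    stop("geometry sidecar lacks mandatory attributes: ",
         paste(miss, collapse = ", "))
  lines <- readLines(path)
  mat <- vapply(lines, function(l) as.double(strsplit(l, ",")[[1]]),
                numeric(length(strsplit(lines[1], ",")[[1]])))
  g <- new("ScanGeometry", modality = meta$modality,
           angles = as.numeric(meta$angles_deg),
           sad = as.numeric(meta$sad_mm %||% NA_real_),
           sdd = as.numeric(meta$sdd_mm %||% NA_real_),
           detCount = as.integer(meta$det_count),
           detPitch = as.numeric(meta$det_pitch_um),
           volShape = as.integer(meta$vol_shape),
           voxelSize = as.numeric(meta$voxel_size_um))
  if (length(meta$angles_deg) != length(lines))
    stop("sinogram rows do not match the sidecar angle list")
  data <- array(as.double(mat), dim = c(g@detCount, length(g@angles)))
  new("ProjectionSet", data = data, geometry = g,
      i0 = as.numeric(meta$i0 %||% NA_real_),
      frames = as.integer(meta$frames %||% 1L))
}

#' Write a run manifest
#'
#' Records the tool version, the configuration snapshot, the seeds, and the
#' MD5 hashes of the listed output files, so that every study output is
#' traceable and re-runnable.
#'
#' @param path manifest path (JSON).
#' @param config configuration list to snapshot.
#' @param seeds named list of seeds.
#' @param files character vector of files to hash.
#' @return the path, invisibly.
#' @export
writeManifest <- function(path, config = list(), seeds = list(),
                          files = character()) {
  hashes <- if (length(files))
    as.list(tools::md5sum(files[file.exists(files)])) else list()
  cfg <- lapply(config, function(x) if (isS4(x)) NULL else x)
  jsonlite::write_json(list(
    tool = "tomomorph",
    version = as.character(utils::packageVersion("tomomorph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[!vapply(cfg, is.null, TRUE)],
    seeds = seeds, file_md5 = hashes),
    path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
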