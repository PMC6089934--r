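#' @include AllClasses.R
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream seed from a base seed; stays below 2^31.
deriveSeed <- function(base, k) {
  as.integer((as.double(base) * 7919 + as.double(k) * 104729) %% 2147483629)
}

as3d <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

# logical array helpers keeping dim attributes
maskLike <- function(x, value) array(value, dim = dim(x))

dice <- function(a, b) {
  2 * sum(a & b) / (sum(a) + sum(b))
}

# Squared Euclidean distance (voxel units) to the nearest TRUE voxel.
sedt <- function(mask) {
  d <- dim(mask)
  array(cpp_sedt(as.logical(mask), d[1], d[2], d[3]), dim = d)
}

# Binary dilation / erosion with a Euclidean ball of radius r (voxel units).
dilateBall <- function(mask, r) {
  if (r <= 0) return(mask)
  sedt(mask) <= r^2 + 1e-9
}

erodeBall <- function(mask, r) {
  if (r <= 0) return(mask)
  sedt(!mask) > r^2 + 1e-9
}

# Cubic box mean filter, border-clipped.
boxFilter <- function(x, r) {
  d <- dim(x)
  array(cpp_box_filter(as.double(x), d[1], d[2], d[3], as.integer(r)), dim = d)
}

medianFilter3 <- function(x, r) {
  d <- dim(x)
  array(cpp_median_filter(as.double(x), d[1], d[2], d[3], as.integer(r)),
        dim = d)
}

labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label_components(as.logical(mask), d[1], d[2], d[3],
                             as.integer(connectivity)), dim = d)
}
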