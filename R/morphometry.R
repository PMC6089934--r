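#' @include AllClasses.R utils.R
NULL

#' Local thickness map
#'
#' Direct-3D model of structure thickness: every foreground voxel is assigned
#' the diameter of the largest sphere that contains it and fits entirely in
#' the foreground (computed by exact inscribed-sphere painting over the
#' Euclidean distance transform). A single-slice mask degenerates to the
#' inscribed-disc definition. Volume borders do not count as background, so
#' structures may touch the border without being thinned.
#'
#' @param mask logical array (or matrix), the foreground phase.
#' @param voxelSize voxel size in um (default 1: thickness in voxels).
#' @return numeric array: thickness in um on foreground voxels, 0 elsewhere.
#' @export
localThickness <- function(mask, voxelSize = 1) {
  mask <- as3d(mask)
  if (!any(mask)) stop("empty mask")
  d <- dim(mask)
  th <- cpp_local_thickness(as.logical(mask), d[1], d[2], d[3])
  array(th * voxelSize, dim = d)
}

#' Bone volume fraction
#'
#' Percentage of VOI voxels classified as bone: 100 * |mask & voi| / |voi|.
#'
#' @param mask logical bone mask.
#' @param voi logical volume-of-interest mask (non-empty).
#' @return BV/TV in percent.
#' @examples
#' boneVolumeFraction(matrix(c(TRUE, FALSE), 4, 4), matrix(TRUE, 4, 4))  # 50
#' @export
boneVolumeFraction <- function(mask, voi) {
  if (sum(voi) == 0) stop("empty VOI")
  100 * sum(mask & voi) / sum(voi)
}

#' Mean trabecular thickness
#'
#' Volume-weighted mean of the local thickness map over the foreground phase.
#'
#' @param mask logical bone mask.
#' @param voxelSize voxel size in um.
#' @return Tb.Th in um.
#' @export
trabecularThickness <- function(mask, voxelSize = 1) {
  th <- localThickness(mask, voxelSize)
  mean(th[as3d(mask)])
}

#' Mean trabecular separation
#'
#' Thickness of the spaces between trabeculae: the local-thickness mean of the
#' complement of the bone mask within the VOI (inversion duality:
#' tb_s(mask, voi) = tb_th(voi & !mask)).
#'
#' @param mask logical bone mask.
#' @param voi logical VOI mask.
#' @param voxelSize voxel size in um.
#' @return Tb.S in um.
#' @export
trabecularSeparation <- function(mask, voi, voxelSize = 1) {
  trabecularThickness(as3d(voi) & !as3d(mask), voxelSize)
}

#' Subchondral plate thickness
#'
#' Mean local thickness of the (cleaned) plate mask.
#'
#' @param plateMask logical plate mask.
#' @param voxelSize voxel size in um.
#' @return Pl.Th in um.
#' @export
plateThickness <- function(plateMask, voxelSize = 1) {
  trabecularThickness(plateMask, voxelSize)
}

#' Trabecular number (direct-model identity)
#'
#' Linear density of trabeculae: Tb.N = (BV/TV as a fraction) / (Tb.Th in mm).
#' With BV/TV 51.9 percent and Tb.Th 214.7 um this gives 2.42 per mm.
#'
#' @param bvtvPct bone volume fraction in percent.
#' @param tbthUm mean trabecular thickness in um (> 0).
#' @return Tb.N in 1/mm.
#' @examples
#' round(trabecularNumber(51.9, 214.7), 2)  # 2.42
#' @export
trabecularNumber <- function(bvtvPct, tbthUm) {
  if (any(tbthUm <= 0)) stop("Tb.Th must be positive")
  (bvtvPct / 100) / (tbthUm / 1000)
}

# Fibonacci sphere: m roughly uniform unit directions.
fibonacciSphere <- function(m) {
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Small random rotation: Rodrigues formula about a random axis.
smallRotation <- function(maxAngle = 0.5) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.05, maxAngle)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Does the ellipsoid (center c0, rotation R, semi-axes s) fit inside the
# foreground? Checked on precomputed unit-sphere surface points; points
# falling outside the array count as background.
ellipsoidFits <- function(mask, d, c0, R, s, dirs) {
  pts <- dirs %*% (t(R) * s)       # == (R %*% diag(s) %*% t(dirs))'
  px <- round(c0[1] + pts[, 1]); py <- round(c0[2] + pts[, 2])
  pz <- round(c0[3] + pts[, 3])
  if (any(px < 1 | px > d[1] | py < 1 | py > d[2] | pz < 1 | pz > d[3]))
    return(FALSE)
  all(mask[cbind(px, py, pz)])
}

#' Ellipsoid factor
#'
#' Rates how prolate (rod-like) or oblate (plate-like) the trabeculae are.
#' Candidate ellipsoids are seeded at distance-ridge (medial-axis) points of
#' the mask (subsampled by a fixed stride in scan order), initialized as the
#' largest inscribed sphere, and grown by axis dilation with a shrinking
#' step, consulting a fixed bank of small rotations (drawn once from `seed`)
#' when growth stalls -- deterministic given the mask and seed. With sorted
#' semi-axes
#' a <= b <= c, EF = a/b - b/c in (-1, 1): positive for prolate rods,
#' negative for oblate plates (the standard convention; set
#' `signConvention = -1` to report the opposite sign). Every foreground voxel
#' takes the EF of the largest ellipsoid containing it and the mean is
#' volume-weighted over assigned voxels.
#'
#' @param mask logical array.
#' @param voxelSize voxel size (um); EF itself is scale-free.
#' @param nSeeds skeleton-point subsampling cap (default 200).
#' @param seed random seed of the stochastic search.
#' @param signConvention +1 (prolate positive, default) or -1.
#' @return list(meanEF, map) where map holds per-voxel EF (NA where no
#'   ellipsoid reached).
#' @export
ellipsoidFactor <- function(mask, voxelSize = 1, nSeeds = 200L, seed = 1L,
                            signConvention = 1) {
  mask <- as3d(mask)
  d <- dim(mask)
  ridge <- array(cpp_distance_ridge(as.logical(mask), d[1], d[2], d[3]),
                 dim = d)
  seeds <- which(ridge)
  if (length(seeds) == 0L) stop("empty skeleton: no ridge points in the mask")
  r2bg <- sedt(!mask)
  dirs <- fibonacciSphere(92L)
  # deterministic seed subsampling: a fixed stride through scan order keeps
  # seed locations stable between slightly different masks of the same object
  if (length(seeds) > nSeeds)
    seeds <- seeds[unique(round(seq(1, length(seeds), length.out = nSeeds)))]
  # fixed orientation bank drawn once from `seed`: identical proposals for
  # every seed point and every mask, so the search itself is deterministic
  bank <- withSeed(seed, lapply(seq_len(24L), function(i) smallRotation(0.6)))
  ells <- lapply(seeds, function(ix) {
    c0 <- as.double(arrayInd(ix, d))
    r0 <- max(sqrt(r2bg[ix]) - 0.5, 0.45)
    R <- diag(3)
    # shrink the seed sphere until it fits the voxelized boundary
    while (r0 > 0.5 && !ellipsoidFits(mask, d, c0, R, rep(r0, 3), dirs))
      r0 <- r0 * 0.85
    s <- rep(r0, 3)
    step <- 1.0
    bankIdx <- 1L
    for (it in 1:60) {
      improved <- FALSE
      for (ax in 1:3) {
        sTry <- s
        sTry[ax] <- s[ax] + step
        if (ellipsoidFits(mask, d, c0, R, sTry, dirs)) {
          s <- sTry
          improved <- TRUE
        }
      }
      if (!improved) {
        rotated <- FALSE
        while (bankIdx <= length(bank)) {
          Rt <- bank[[bankIdx]] %*% R
          bankIdx <- bankIdx + 1L
          if (ellipsoidFits(mask, d, c0, Rt, s, dirs)) {
            R <- Rt
            rotated <- TRUE
            break
          }
        }
        if (!rotated) {
          step <- step / 2
          if (step < 0.12) break
        }
      }
    }
    o <- sort(s)
    list(center = c0, R = R, s = s,
         ef = signConvention * (o[1] / o[2] - o[2] / o[3]),
         vol = prod(s))
  })
  efMap <- array(NA_real_, dim = d)
  ord <- order(vapply(ells, `[[`, 0, "vol"), decreasing = TRUE)
  for (e in ells[ord]) {
    R <- e$R; s <- e$s; c0 <- e$center
    Rbox <- ceiling(max(s))
    rng <- lapply(1:3, function(ax)
      max(1L, floor(c0[ax] - Rbox)):min(d[ax], ceiling(c0[ax] + Rbox)))
    box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    rel <- t(t(box) - c0)
    local <- rel %*% R            # coordinates in the ellipsoid frame
    inside <- rowSums((t(t(local) / s))^2) <= 1
    sel <- box[inside, , drop = FALSE]
    if (nrow(sel) == 0L) next
    ok <- mask[sel] & is.na(efMap[sel])
    efMap[sel[ok, , drop = FALSE]] <- e$ef
  }
  assigned <- !is.na(efMap) & mask
  meanEF <- if (any(assigned)) mean(efMap[assigned]) else NA_real_
  list(meanEF = meanEF, map = efMap)
}

#' All six morphometric parameters of one sample
#'
#' BV/TV, Tb.Th, Tb.S (on the trabecular mask within the VOI), Tb.N via the
#' direct-model identity from the measured BV/TV and Tb.Th, EF on the
#' trabecular mask, and Pl.Th on the plate mask. Single-slice masks are
#' extruded to `efExtrude` copies along z for the (three-axis) EF search; the
#' other parameters are computed in-plane.
#'
#' @param trabMask logical trabecular bone mask.
#' @param plateMask logical plate mask (all-FALSE: Pl.Th is NA).
#' @param voi logical trabecular VOI.
#' @param voxelSize voxel size in um.
#' @param efSeeds,efSeed ellipsoid factor search size / seed.
#' @param efExtrude extrusion depth for single-slice EF (default 4).
#' @return A [MorphometryResult-class].
#' @export
computeMorphometry <- function(trabMask, plateMask, voi, voxelSize = 25,
                               efSeeds = 200L, efSeed = 1L, efExtrude = 4L) {
  trabMask <- as3d(trabMask); plateMask <- as3d(plateMask); voi <- as3d(voi)
  bone <- trabMask & voi
  bv <- boneVolumeFraction(trabMask, voi)
  tbth <- if (any(bone)) trabecularThickness(bone, voxelSize) else 0
  tbs <- if (any(voi & !trabMask)) trabecularSeparation(trabMask, voi, voxelSize)
         else 0
  tbn <- if (tbth > 0) trabecularNumber(bv, tbth) else 0
  efMask <- bone
  if (dim(efMask)[3] == 1L && any(efMask))
    efMask <- array(rep(efMask, efExtrude),
                    dim = c(dim(efMask)[1:2], efExtrude))
  ef <- if (any(efMask))
    ellipsoidFactor(efMask, voxelSize, nSeeds = efSeeds, seed = efSeed)$meanEF
  else NA_real_
  plth <- if (any(plateMask)) plateThickness(plateMask, voxelSize)
          else NA_real_
  new("MorphometryResult", bvtv = bv, tbth = tbth, tbs = tbs, tbn = tbn,
      ef = min(max(ef, -1), 1), plth = plth)
}
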