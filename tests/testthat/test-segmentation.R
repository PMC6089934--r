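test_that("prefilter leaves constants alone and removes impulses", {
  const <- VoxelVolume(array(3.7, c(12, 12, 6)), 25)
  out <- prefilterVolume(const)
  expect_equal(voxelData(out), voxelData(const))

  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 100
  med <- prefilterVolume(VoxelVolume(imp, 25),
                         SegmentationConfig(unsharpAmount = 0))
  expect_equal(max(abs(voxelData(med))), 0)
})

test_that("unsharp masking overshoots a step edge as the 1D model predicts", {
  # step along x, constant in y/z: the chain reduces to 1D
  n <- 24L
  v <- array(rep(c(rep(0, 12), rep(1, 12)), n * 3), dim = c(n, n, 3))
  v <- aperm(v, c(1, 2, 3))
  cfg <- SegmentationConfig(medianRadius = 0)
  out <- prefilterVolume(v, cfg)
  # hand-computed 1D profile: u + 0.5 * (u - boxmean3(u)); interior rows only
  u <- c(rep(0, 12), rep(1, 12))
  box <- vapply(seq_len(n), function(i)
    mean(u[max(1, i - 1):min(n, i + 1)]), 0)
  expected <- u + 0.5 * (u - box)
  mid <- out[, 12, 2]
  expect_equal(as.double(mid), expected, tolerance = 1e-12)
  # overshoot on both sides of the step
  expect_lt(expected[12], 0)
  expect_gt(expected[13], 1)
})

test_that("Otsu equals the exhaustive between-class-variance argmax", {
  set.seed(14)
  for (rep in 1:4) {
    u <- array(c(rnorm(400, 10, 2), rnorm(300, 30, 4), rnorm(100, 60, 5)),
               dim = c(20, 20, 2))
    expect_equal(otsuThreshold(u), bruteOtsu(u))
  }

  # two equal-mass spikes: threshold strictly between them
  u2 <- array(rep(c(50, 200), each = 500), dim = c(10, 10, 10))
  thr <- otsuThreshold(u2)
  expect_gt(thr, 50)
  expect_lte(thr, 200)

  # affine intensity rescaling maps the threshold affinely (same binning)
  u <- array(rnorm(1000), dim = c(10, 10, 10))
  t1 <- otsuThreshold(u)
  t2 <- otsuThreshold(3 * u + 7)
  expect_equal(t2, 3 * t1 + 7, tolerance = 1e-9)

  expect_error(otsuThreshold(array(1, c(4, 4, 4))), "constant")
})

test_that("despeckling keeps the largest component with a documented tie rule", {
  m <- array(FALSE, c(20, 20, 1))
  m[2:11, 2:11, 1] <- TRUE          # 100 voxels
  m[15:16, 15:16, 1] <- TRUE        # 4 voxels
  out <- despeckleKeepLargest(m)
  expect_equal(sum(out), 100)
  expect_true(all(out[2:11, 2:11, 1]))

  # single component: identity
  single <- array(FALSE, c(8, 8, 1)); single[2:4, 2:4, 1] <- TRUE
  expect_identical(despeckleKeepLargest(single), single)

  # two equal components: lexicographic-first kept
  tie <- array(FALSE, c(20, 8, 1))
  tie[2:4, 2:4, 1] <- TRUE
  tie[12:14, 2:4, 1] <- TRUE
  out2 <- despeckleKeepLargest(tie)
  expect_true(all(out2[2:4, 2:4, 1]))
  expect_false(any(out2[12:14, 2:4, 1]))

  expect_error(despeckleKeepLargest(array(FALSE, c(4, 4, 1))), "empty")

  # min-size variant keeps every component at or above the cutoff
  out3 <- despeckleMinSize(m, minSize = 4L)
  expect_identical(out3, m)
  out4 <- despeckleMinSize(m, minSize = 5L)
  expect_equal(sum(out4), 100)
})

test_that("plate cleanup fills pores and closes small notches", {
  cfg <- SegmentationConfig(closingRadius = 3L)

  # solid slab: fixed point
  slab <- array(FALSE, c(24, 24, 9)); slab[, , 3:7] <- TRUE
  expect_identical(cleanPlate(slab, cfg), slab)

  # interior spherical void: filled
  holed <- slab
  for (i in 10:14) for (j in 10:14) for (k in 4:6)
    if ((i - 12)^2 + (j - 12)^2 + (k - 5)^2 <= 4) holed[i, j, k] <- FALSE
  expect_identical(cleanPlate(holed, cfg), slab)

  # hemispherical edge notches: a small one (r = 2) is closed, a large one
  # (r = 6) survives
  notched <- slab
  small <- function(i, j, k) (i - 6)^2 + (j - 6)^2 + (k - 3)^2 <= 2^2
  large <- function(i, j, k) (i - 18)^2 + (j - 18)^2 + (k - 3)^2 <= 6^2
  for (i in 1:24) for (j in 1:24) for (k in 3:7) {
    if (small(i, j, k)) notched[i, j, k] <- FALSE
    if (large(i, j, k)) notched[i, j, k] <- FALSE
  }
  cleaned <- cleanPlate(notched, cfg)
  # the small pit is healed below the surface layer (the closing ball dips
  # 3 - sqrt(3^2 - 2^2) < 1 voxel into the opening)
  expect_true(all(cleaned[4:8, 4:8, 4:5]))
  expect_false(all(cleaned[17:19, 17:19, 3:5]))   # large notch remains
})

test_that("segmenting a noiseless discrete phantom recovers the bone exactly", {
  # a single connected slab: keep-largest cannot discard real structure
  spec <- PhantomSpec(c(24L, 24L, 15L), structure = "plate")
  ph <- makePlatePhantom(225, 300, spec)
  truthBone <- phantomLabels(ph$truth) == 2L
  masks <- segmentBone(ph$volume, list(trabecular = array(TRUE, dim(truthBone)),
                                       plate = NULL))
  expect_identical(masks$trabecular, truthBone)   # Dice exactly 1

  expect_error(segmentBone(ph$volume,
                           list(trabecular = array(FALSE, dim(truthBone)))),
               "empty")
})

test_that("segmentation of a full-data reconstruction matches ground truth", {
  ph <- threeClassPhantom(64L)
  g <- buildGeometry("fan2d", nAngles = 180, stepDeg = 1.05,
                     lattice = ph$volume)
  fdk <- reconstructFDK(addNoise(forwardProject(ph$volume, g), 3e4, 2L,
                                 seed = 2))
  truthBone <- ph$labels == 2L
  masks <- segmentBone(fdk, list(trabecular = array(TRUE, dim(truthBone)),
                                 plate = NULL))
  dice <- 2 * sum(masks$trabecular & truthBone) /
    (sum(masks$trabecular) + sum(truthBone))
  expect_gt(dice, 0.95)

  # segmenting an already binary volume returns it up to despeckling (the
  # edge-reshaping prefilter stages disabled)
  binvol <- VoxelVolume(array(as.double(truthBone), dim(truthBone)), 25)
  again <- segmentBone(binvol, list(trabecular = array(TRUE, dim(truthBone)),
                                    plate = NULL),
                       SegmentationConfig(medianRadius = 0L,
                                          unsharpAmount = 0))
  expect_identical(again$trabecular, despeckleKeepLargest(truthBone))
})

test_that("pore filling never flips voxels outside the component rules", {
  set.seed(31)
  m <- array(runif(24 * 24 * 8) < 0.6, c(24, 24, 8))
  cfg <- SegmentationConfig(closingRadius = 0L)
  filled <- cleanPlate(m, cfg)
  # filling only adds foreground, never removes it
  expect_true(all(filled[m]))
  # added voxels are exactly the interior background components
  lab <- tomomorph:::labelComponents(!m, 6L)
  border <- array(FALSE, dim(m))
  border[c(1, 24), , ] <- TRUE; border[, c(1, 24), ] <- TRUE
  border[, , c(1, 8)] <- TRUE
  interior <- !m & !(lab %in% unique(lab[border & !m]))
  expect_equal(sum(filled) - sum(m), sum(interior))
})
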