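test_that("apodized ramp filter vanishes at zero frequency", {
  expect_equal(rampFilterResponse(0), 0)
  expect_equal(rampFilterResponse(0, alpha = 0.8), 0)
  expect_equal(rampFilterResponse(1, alpha = 0.54), 1 * (0.54 - 0.46))
})

test_that("filtered backprojection recovers a uniform disc", {
  vol <- discPhantom(128L, 40)
  inside <- discInterior(128L, 35)

  # dense 360-view fan scan
  gf <- buildGeometry("fan2d", nAngles = 360, stepDeg = 1, lattice = vol)
  rf <- reconstructFDK(forwardProject(vol, gf))
  expect_lt(abs(mean(voxelData(rf)[inside]) - 0.1) / 0.1, 0.05)

  # Parker-weighted short scan at the micro-CT protocol's span
  gs <- buildGeometry("fan2d", nAngles = 260, stepDeg = 0.7, lattice = vol)
  rs <- reconstructFDK(forwardProject(vol, gs))
  expect_lt(abs(mean(voxelData(rs)[inside]) - 0.1) / 0.1, 0.05)

  # parallel-beam 180-degree scan
  gp <- buildGeometry("parallel2d", nAngles = 180, stepDeg = 1, lattice = vol)
  rp <- reconstructFDK(forwardProject(vol, gp))
  expect_lt(abs(mean(voxelData(rp)[inside]) - 0.1) / 0.1, 0.05)

  # zero sinogram reconstructs to exactly zero (linearity)
  zero <- forwardProject(VoxelVolume(array(0, dim(vol)), voxelSize(vol)), gf)
  expect_true(all(voxelData(reconstructFDK(zero)) == 0))

  # insufficient angular coverage is an error naming the deficit
  gshort <- buildGeometry("fan2d", nAngles = 100, stepDeg = 0.7,
                          lattice = vol)
  expect_error(reconstructFDK(forwardProject(vol, gshort)), "deficit")
})

test_that("FDK reconstructs a cone-beam ball to the right attenuation", {
  n <- 48L
  ball <- array(0.1 * ballMask(n, 14), dim = c(n, n, n))
  vol <- VoxelVolume(ball, 25)
  g <- buildGeometry("cone3d", nAngles = 180, stepDeg = 2, lattice = vol)
  r <- reconstructFDK(forwardProject(vol, g))
  core <- ballMask(n, 10)
  expect_lt(abs(mean(voxelData(r)[core]) - 0.1) / 0.1, 0.07)
})

test_that("CGLS solves small dense systems like a direct solver", {
  set.seed(2)
  M <- matrix(rnorm(20 * 16), 20, 16)
  b <- rnorm(20)
  gd <- buildGeometry("parallel2d", nAngles = 1, stepDeg = 1, detCount = 20L,
                      lattice = c(16L, 1L, 1L))
  A <- new("TomoOperator",
           forward = function(x) as.double(M %*% x),
           adjoint = function(y) as.double(crossprod(M, y)),
           volDim = c(16L, 1L, 1L), projDim = c(20L, 1L))
  ps <- new("ProjectionSet", data = matrix(b, 20, 1), geometry = gd,
            i0 = NA_real_, frames = 1L)
  x <- reconstructCGLS(ps, A, ReconConfig("cgls", nIter = 16L))
  xs <- qr.solve(M, b)
  expect_lt(sqrt(sum((as.double(voxelData(x)) - xs)^2)) / sqrt(sum(xs^2)),
            1e-6)

  # zero data -> zero volume
  ps0 <- new("ProjectionSet", data = matrix(0, 20, 1), geometry = gd,
             i0 = NA_real_, frames = 1L)
  expect_true(all(voxelData(reconstructCGLS(ps0, A)) == 0))

  # residual norms are non-increasing
  res <- attr(x, "residuals")
  expect_true(all(diff(res) <= 1e-10 * res[1]))

  ps@data[1, 1] <- NA_real_
  expect_error(validObject(ps), "finite")
})

test_that("CGLS residuals are monotone on tomographic data", {
  vol <- discPhantom(48L, 16)
  g <- buildGeometry("fan2d", nAngles = 40, stepDeg = 4.6, lattice = vol)
  p <- addNoise(forwardProject(vol, g), 1e4, 2L, seed = 3)
  r <- reconstructCGLS(p, config = ReconConfig("cgls", nIter = 25L))
  res <- attr(r, "residuals")
  expect_true(all(diff(res) <= 1e-10 * res[1]))
})

test_that("TV with zero weight equals plain least-squares descent", {
  vol <- discPhantom(32L, 10)
  g <- buildGeometry("fan2d", nAngles = 30, stepDeg = 6.2, lattice = vol)
  p <- forwardProject(vol, g)
  op <- tomoOperator(geometry(p))
  tv0 <- reconstructTV(p, op, ReconConfig("tv", tvLambda = 0, nIter = 15L))

  # independent plain-R BB gradient descent on 1/2 ||Au - b||^2 with the
  # same step rule (exact first step, BB1 after, 5-step nonmonotone guard)
  A <- function(x) as.double(op@forward(x))
  At <- function(y) as.double(op@adjoint(y))
  b <- as.double(projData(p))
  u <- numeric(prod(op@volDim))
  gr <- At(A(u) - b)
  alpha0 <- sum(gr^2) / sum(A(gr)^2)
  alpha <- alpha0
  objs <- 0.5 * sum(b^2)
  best <- u; bestObj <- objs
  for (it in 1:15) {
    ref <- max(utils::tail(objs, 5))
    repeat {
      uN <- u - alpha * gr
      objN <- 0.5 * sum((A(uN) - b)^2)
      if (objN <= ref) break
      alpha <- alpha / 2
    }
    grN <- At(A(uN) - b)
    s <- uN - u; y <- grN - gr
    alpha <- if (sum(s * y) > 0) sum(s^2) / sum(s * y) else alpha0
    alpha <- min(max(alpha, 1e-8), 1e8)
    u <- uN; gr <- grN
    objs <- c(objs, objN)
    if (objN < bestObj) { best <- u; bestObj <- objN }
  }
  expect_lt(max(abs(as.double(voxelData(tv0)) - best)),
            1e-6 * max(abs(best)))
})

test_that("a very large TV weight flattens the reconstruction", {
  vol <- discPhantom(32L, 10)
  g <- buildGeometry("fan2d", nAngles = 30, stepDeg = 6.2, lattice = vol)
  p <- addNoise(forwardProject(vol, g), 1e5, 2L, seed = 2)
  op <- tomoOperator(geometry(p))
  cg <- reconstructCGLS(p, op)
  scale <- max(abs(as.double(op@adjoint(as.double(projData(p))))))
  tvBig <- reconstructTV(p, op, ReconConfig("tv", tvLambda = 1e6 * scale))
  expect_lt(totalVariation(tvBig), 0.01 * totalVariation(cg))
  expect_error(reconstructTV(p, op, ReconConfig("tv", tvEpsilon = -1)),
               "positive")
})

test_that("TV beats CGLS on a sparse noisy piecewise-constant phantom", {
  ph <- threeClassPhantom(48L)
  g <- buildGeometry("fan2d", nAngles = 264, stepDeg = 0.687,
                     lattice = ph$volume)
  p <- subsampleProjections(
    addNoise(forwardProject(ph$volume, g), 5e3, 2L, seed = 6), 6)
  op <- tomoOperator(geometry(p))
  truth <- as.double(voxelData(ph$volume))
  rmse <- function(v) sqrt(mean((as.double(voxelData(v)) - truth)^2))
  cg <- reconstructCGLS(p, op)
  g0 <- as.double(op@adjoint(as.double(projData(p))))
  lam <- stats::quantile(abs(g0), 0.999) * 3e-3
  tv <- reconstructTV(p, op, ReconConfig("tv", tvLambda = lam))
  expect_lte(rmse(tv), rmse(cg))

  # objective never ends above its starting value
  expect_lte(utils::tail(attr(tv, "objective"), 1)[1],
             attr(tv, "objective")[1])
})

test_that("TV penalty is non-increasing along the lambda grid", {
  vol <- discPhantom(32L, 10)
  g <- buildGeometry("fan2d", nAngles = 40, stepDeg = 4.6, lattice = vol)
  p <- addNoise(forwardProject(vol, g), 1e4, 2L, seed = 4)
  op <- tomoOperator(geometry(p))
  grid <- defaultLambdaGrid(p, op, nPoints = 5L)
  pen <- vapply(grid, function(l)
    totalVariation(reconstructTV(p, op, ReconConfig("tv", tvLambda = l))), 0)
  expect_true(all(diff(pen) <= 0.05 * pen[1]))
})

test_that("the L-curve corner picker finds analytic corners", {
  # ideal L: vertical branch then horizontal branch with a sharp vertex
  lam <- 10^seq(-3, 3, length.out = 7)
  res <- c(1, 1, 1, 1, 10, 100, 1000)
  pen <- c(1000, 100, 10, 1, 1, 1, 1)
  out <- lcurveCorner(lam, res, pen)
  expect_equal(out$lambda, lam[4])

  # collinear log-log points: zero curvature everywhere, smallest lambda wins
  lam3 <- c(0.1, 1, 10)
  out3 <- lcurveCorner(lam3, c(1, 10, 100), c(100, 10, 1))
  expect_true(all(out3$curvatures == 0))
  expect_equal(out3$lambda, 0.1)

  # degenerate grids fall back with a warning
  expect_warning(out1 <- lcurveCorner(5, 1, 1), "fewer than 3")
  expect_equal(out1$lambda, 5)
})

test_that("DART returns prior gray values only and recovers a discrete phantom", {
  gray <- c(0, 0.038, 0.18)
  ph <- threeClassPhantom(64L, gray)
  g <- buildGeometry("fan2d", nAngles = 64, stepDeg = 2.9, lattice = ph$volume)
  p <- forwardProject(ph$volume, g)   # noiseless
  op <- tomoOperator(geometry(p))
  prior <- GrayPrior(gray)

  dart <- reconstructDART(p, op, prior, ReconConfig("dart", seed = 5L))
  vals <- unique(as.double(voxelData(dart)))
  expect_true(all(vals %in% gray))

  # misclassification below 1 percent on the noiseless fixture
  mis <- mean(voxelData(dart) != voxelData(ph$volume))
  expect_lt(mis, 0.01)

  # and strictly better than segmenting the initial CGLS reconstruction
  init <- reconstructCGLS(p, op, ReconConfig("cgls", nIter = 25L))
  initSeg <- gray[tomomorph:::classifyPrior(voxelData(init), prior) + 1L]
  misInit <- mean(initSeg != as.double(voxelData(ph$volume)))
  expect_lt(mis, misInit)

  # determinism under a fixed seed
  dart2 <- reconstructDART(p, op, prior, ReconConfig("dart", seed = 5L))
  expect_identical(voxelData(dart), voxelData(dart2))

  # continuous iterate is exposed behind the flag
  cont <- reconstructDART(p, op, prior,
                          ReconConfig("dart", seed = 5L,
                                      dartContinuous = TRUE))
  expect_gt(length(unique(as.double(voxelData(cont)))), 3)

  expect_error(GrayPrior(c(0, 0.038, 0.18), thresholds = c(0.1, 0.12)),
               "ordering")
})

test_that("contrast-to-noise ratio follows its definition", {
  set.seed(8)
  sl <- matrix(20 + rnorm(900, sd = 10), 30, 30)
  sl[1:10, 1:10] <- 100
  v <- VoxelVolume(array(sl, c(30, 30, 1)), 25)
  bone <- array(FALSE, c(30, 30, 1)); bone[1:10, 1:10, 1] <- TRUE
  bg <- array(FALSE, c(30, 30, 1)); bg[20:30, 20:30, 1] <- TRUE
  cnr <- computeCNR(v, bone, bg)
  slice <- sl
  expect_equal(cnr, (mean(slice[1:10, 1:10]) - mean(slice[20:30, 20:30])) /
                      sd(slice[20:30, 20:30]))

  # identical ROI statistics give zero
  v2 <- VoxelVolume(array(c(rep(5, 450), 5 + rnorm(450)), c(30, 30, 1)), 25)
  # constant background is flagged undefined
  vconst <- VoxelVolume(array(0, c(30, 30, 1)), 25)
  expect_identical(computeCNR(vconst, bone, bg), Inf)
  expect_error(computeCNR(v, bone, bone), "disjoint")
  tiny <- array(FALSE, c(30, 30, 1)); tiny[1:4, 1:4, 1] <- TRUE
  expect_error(computeCNR(v, tiny, bg), "25")
})
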