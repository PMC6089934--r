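test_that("uniform geometries report the documented angular span", {
  g <- buildGeometry("parallel2d", nAngles = 260, stepDeg = 0.7,
                     lattice = c(16L, 16L, 1L))
  expect_equal(angularSpan(g), 181.3)
  expect_equal(length(viewAngles(g)), 260L)

  g1 <- buildGeometry("parallel2d", nAngles = 1, stepDeg = 1,
                      lattice = c(16L, 16L, 1L))
  expect_equal(angularSpan(g1), 0)

  g2 <- buildGeometry("parallel2d", nAngles = 61, stepDeg = 3,
                      lattice = c(16L, 16L, 1L))
  expect_equal(angularSpan(g2), 180)

  expect_warning(
    buildGeometry("fan2d", nAngles = 10, stepDeg = 20, detCount = 16L,
                  lattice = c(64L, 64L, 1L)),
    "shadow")
})

test_that("forward projection matches its definition", {
  g <- buildGeometry("parallel2d", nAngles = 4, stepDeg = 45,
                     lattice = c(17L, 17L, 1L))
  zero <- VoxelVolume(array(0, c(17, 17, 1)), 25)
  expect_true(all(projData(forwardProject(zero, g)) == 0))

  # single unit voxel at the isocenter: axis-aligned views read one voxel
  # path length (25 um = 0.025 mm); oblique views within the interpolation
  # model's sqrt(2) factor
  v <- array(0, c(17, 17, 1)); v[9, 9, 1] <- 1
  p <- projData(forwardProject(VoxelVolume(v, 25), g))
  centre <- (nrow(p) + 1) %/% 2
  expect_equal(p[centre, c(1, 3)], c(0.025, 0.025), tolerance = 1e-12)
  expect_lt(max(abs(p[centre, ] - 0.025)), 0.025 * (sqrt(2) - 1) + 1e-9)

  # 8x8 grid, 4 angles: elementwise agreement with an explicitly assembled
  # dense system matrix
  n <- 8L
  gd <- buildGeometry("parallel2d", nAngles = 4, stepDeg = 40, startDeg = 10,
                      detCount = 13L, lattice = c(n, n, 1L))
  Ad <- denseParallelMatrix(n, viewAngles(gd), 13L, 1, 0.025)
  set.seed(42)
  x <- array(rnorm(n * n), dim = c(n, n, 1))
  p1 <- as.double(projData(forwardProject(VoxelVolume(x, 25), gd)))
  expect_lt(max(abs(p1 - as.double(Ad %*% as.double(x)))), 1e-10)

  # dense-matrix transpose oracle for the adjoint
  set.seed(43)
  y <- rnorm(nrow(Ad))
  bp <- backProject(new("ProjectionSet",
                        data = matrix(y, 13L, 4L), geometry = gd,
                        i0 = NA_real_, frames = 1L))
  expect_lt(max(abs(as.double(voxelData(bp)) - as.double(crossprod(Ad, y)))),
            1e-10)
})

test_that("forward/adjoint form an exact pair and are linear", {
  geoms <- list(
    buildGeometry("parallel2d", nAngles = 24, stepDeg = 7.5,
                  lattice = c(16L, 16L, 1L)),
    buildGeometry("fan2d", nAngles = 24, stepDeg = 8.2,
                  lattice = c(16L, 16L, 1L)),
    buildGeometry("cone3d", nAngles = 12, stepDeg = 17,
                  lattice = c(10L, 10L, 6L)))
  set.seed(7)
  for (g in geoms) {
    A <- tomoOperator(g)
    x <- rnorm(prod(A@volDim)); x2 <- rnorm(prod(A@volDim))
    y <- rnorm(prod(A@projDim))
    lhs <- sum(A@forward(x) * y)
    rhs <- sum(x * A@adjoint(y))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
    # linearity to 1e-10
    expect_lt(max(abs(A@forward(2.5 * x - 1.25 * x2) -
                      (2.5 * A@forward(x) - 1.25 * A@forward(x2)))), 1e-10)
  }
})

test_that("rotating the phantom by one step shifts parallel projections", {
  set.seed(11)
  v <- matrix(0, 32, 32)
  v[10:22, 12:20] <- 1
  v <- v + matrix(rnorm(32 * 32, sd = 0.01), 32)
  vol <- VoxelVolume(array(v, c(32, 32, 1)), 25)
  # rotate by 90 degrees CCW about the center (exact on the lattice)
  vr <- VoxelVolume(array(t(v)[, 32:1], c(32, 32, 1)), 25)
  g <- buildGeometry("parallel2d", nAngles = 4, stepDeg = 90,
                     lattice = c(32L, 32L, 1L))
  p <- projData(forwardProject(vol, g))
  pr <- projData(forwardProject(vr, g))
  # view k of the rotated phantom equals view k+1 of the original, up to the
  # half-open transverse edge convention of the interpolation model
  for (k in 1:3)
    expect_lt(max(abs(pr[, k] - p[, k + 1])), 0.005 * max(abs(p)))
})

test_that("Poisson noise with frame averaging behaves as specified", {
  g <- buildGeometry("parallel2d", nAngles = 8, stepDeg = 22.5,
                     lattice = c(16L, 16L, 1L))
  vol <- VoxelVolume(array(0.05, c(16, 16, 1)), 25)
  p <- forwardProject(vol, g)

  expect_error(addNoise(p, -1), "positive")

  # vanishing-noise limit
  n0 <- addNoise(p, 1e12, 2L, seed = 1)
  expect_lt(max(abs(projData(n0) - projData(p))),
            1e-3 * max(abs(projData(p))))

  # determinism
  expect_identical(projData(addNoise(p, 1e4, 2L, seed = 9)),
                   projData(addNoise(p, 1e4, 2L, seed = 9)))

  # Monte-Carlo mean within 3 standard errors of the noiseless data
  reps <- 400
  acc <- 0
  for (r in seq_len(reps))
    acc <- acc + projData(addNoise(p, 1e4, 2L, seed = 1000 + r))
  m <- acc / reps
  p0 <- projData(p)
  sdTheory <- sqrt(exp(p0) / (1e4 * 2))     # delta-method SD of one draw
  z <- (m - p0) / (sdTheory / sqrt(reps))
  expect_lt(abs(mean(z)), 3)
})

test_that("view subsampling keeps every k-th view from the first", {
  g <- buildGeometry("parallel2d", nAngles = 260, stepDeg = 0.7,
                     lattice = c(8L, 8L, 1L))
  vol <- VoxelVolume(array(runif(64), c(8, 8, 1)), 25)
  p <- forwardProject(vol, g)
  expect_equal(length(viewAngles(subsampleProjections(p, 2))), 130L)
  expect_equal(length(viewAngles(subsampleProjections(p, 4))), 65L)
  expect_equal(length(viewAngles(subsampleProjections(p, 6))), 44L)
  expect_identical(projData(subsampleProjections(p, 1)), projData(p))
  s6 <- subsampleProjections(p, 6)
  expect_equal(viewAngles(s6)[1], viewAngles(p)[1])
  expect_equal(diff(viewAngles(s6))[1], 0.7 * 6)
  expect_error(subsampleProjections(p, 500), "exceeds")
  expect_error(forwardProject(VoxelVolume(array(0, c(9, 9, 1)), 25), g),
               "lattice")
})
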