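test_that("plate phantoms are built to exact slab geometry", {
  spec <- PhantomSpec(c(32L, 32L, 42L), structure = "plate")
  ph <- makePlatePhantom(225, 300, spec)
  km <- knownMorphometry(ph$truth)
  expect_equal(km$tbth, 225)
  expect_equal(km$tbs, 300)
  expect_equal(km$bvtvAnalytic, 100 * 225 / 525)

  # exactly the three admissible gray values before noise
  expect_setequal(unique(as.double(voxelData(ph$volume))),
                  spec@grayValues[c(1, 2, 3)][-1])  # no background here

  # sub-resolution slabs are rejected
  expect_error(makePlatePhantom(50, 300, spec), "resolution floor")

  # stored BV/TV is recomputed from the labels exactly
  lab <- phantomLabels(ph$truth)
  expect_equal(km$bvtv, 100 * mean(lab == 2L))
})

test_that("rod phantoms are built to exact lattice geometry", {
  spec <- PhantomSpec(c(40L, 40L, 48L), structure = "rod_lattice")
  ph <- makeRodPhantom(100, 500, 3L, spec)
  km <- knownMorphometry(ph$truth)
  expect_equal(km$tbth, 200)
  expect_equal(km$bvtvAnalytic, 100 * pi * 100^2 / 500^2)
  expect_equal(km$efReferenceSign, 1)
  expect_error(makeRodPhantom(100, 150, 3L, spec), "overlap")
  expect_error(makeRodPhantom(30, 500, 3L, spec), "below 2 voxels")
})

test_that("trabecular phantoms hit the target volume fraction deterministically", {
  spec <- PhantomSpec(c(48L, 48L, 48L), structure = "trabecular",
                      structureParams = list(bvtv = 50, corrLength = 150),
                      seed = 21L)
  ph <- makeTrabecularPhantom(spec)
  expect_lt(abs(knownMorphometry(ph$truth)$bvtv - 50), 0.5)

  # same seed, same volume; different seed, different volume
  ph2 <- makeTrabecularPhantom(spec)
  expect_identical(phantomLabels(ph$truth), phantomLabels(ph2$truth))
  spec3 <- spec; spec3@seed <- 22L
  expect_false(identical(phantomLabels(ph$truth),
                         phantomLabels(makeTrabecularPhantom(spec3)$truth)))

  # unreachable targets are rejected at specification time
  expect_error(PhantomSpec(c(32L, 32L, 32L), structure = "trabecular",
                           structureParams = list(bvtv = 100)),
               "0, 100")
  # and a spec mutated past validation is rejected by the generator
  bad <- PhantomSpec(c(32L, 32L, 32L), structure = "trabecular",
                     structureParams = list(bvtv = 50))
  bad@structureParams$bvtv <- 100
  expect_error(makeTrabecularPhantom(bad))

  # three distinct voxel values, equal to the spec's gray values
  expect_setequal(unique(as.double(voxelData(ph$volume))),
                  spec@grayValues[c(2, 3)])  # full-grid mode: no background
})

test_that("anisotropic correlation separates rod-like from plate-like EF", {
  base <- list(bvtv = 30, corrLength = 90)
  rodSpec <- PhantomSpec(c(48L, 48L, 48L), structure = "trabecular",
                         structureParams = c(base,
                                             list(anisotropy = c(0.6, 0.6, 3))),
                         seed = 31L)
  plateSpec <- PhantomSpec(c(48L, 48L, 48L), structure = "trabecular",
                           structureParams = c(base,
                                               list(anisotropy = c(3, 3, 0.6))),
                           seed = 31L)
  efOf <- function(spec) {
    ph <- makeTrabecularPhantom(spec)
    bone <- phantomLabels(ph$truth) == 2L
    ellipsoidFactor(bone, nSeeds = 150L, seed = 5L)$meanEF
  }
  efRod <- efOf(rodSpec)
  efPlate <- efOf(plateSpec)
  expect_gt(efRod, 0)
  expect_lt(efPlate, 0)
})

test_that("cohorts reproduce the printed group statistics", {
  co <- sampleCohort(CohortSpec("control", n = 16L, baseSeed = 4L))
  bv <- vapply(co, function(p) knownMorphometry(p$truth)$bvtv, 0)
  expect_lt(abs(mean(bv) - 51.9), 2.0)

  # degenerate single draw with zero SDs hits the group means
  t0 <- groupTargets("aclt")
  t0 <- lapply(t0, function(x) c(x[1], 0))
  one <- sampleCohort(CohortSpec("aclt", n = 1L, targets = t0, baseSeed = 5L))
  expect_lt(abs(knownMorphometry(one[[1]]$truth)$bvtv - 47.7), 0.5)

  # byte-identical cohorts under a fixed base seed
  coA <- sampleCohort(CohortSpec("aclt", n = 2L, baseSeed = 6L))
  coB <- sampleCohort(CohortSpec("aclt", n = 2L, baseSeed = 6L))
  expect_identical(lapply(coA, function(p) phantomLabels(p$truth)),
                   lapply(coB, function(p) phantomLabels(p$truth)))
})

test_that("slice-mode phantoms carry disc, plate band and region masks", {
  co <- sampleCohort(CohortSpec("aclt", n = 1L, baseSeed = 9L,
                                mode = "slice2d"))
  truth <- co[[1]]$truth
  lab <- phantomLabels(truth)
  reg <- regionMasks(truth)
  expect_true(any(lab == 0L))             # background outside the disc
  expect_gt(sum(reg$plate), 500)
  expect_gt(sum(reg$trabecular), 5000)
  expect_false(any(reg$plate & reg$trabecular))
  # plate region is (pored) bone
  expect_gt(mean(lab[reg$plate] == 2L), 0.9)
  # achieved BV/TV in the analysis region matches the drawn target
  drawn <- knownMorphometry(truth)$drawnTargets$bvtv
  expect_lt(abs(knownMorphometry(truth)$bvtv - drawn), 0.5)
})
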