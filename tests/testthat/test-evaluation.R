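test_that("relative errors follow their definition and aggregate correctly", {
  expect_equal(relativeErrors(c(200, 200), c(200, 200))$perSample, c(0, 0))
  expect_equal(relativeErrors(220, 200)$perSample, 10)

  # three-sample aggregation against a hand computation
  re <- relativeErrors(c(110, 95, 104), c(100, 100, 100))
  expect_equal(re$perSample, c(10, 5, 4))
  expect_equal(re$mean, mean(c(10, 5, 4)))
  expect_equal(re$sd, sd(c(10, 5, 4)))

  # zero references are excluded with a warning
  expect_warning(re0 <- relativeErrors(c(1, 2), c(0, 2)), "zero reference")
  expect_equal(re0$perSample, 0)
  expect_equal(re0$nExcluded, 1L)
})

test_that("the smoke study runs the full grid deterministically", {
  cfg <- studyConfig("smoke", masterSeed = 3L)
  st <- suppressWarnings(runStudy(cfg, verbose = FALSE))
  expect_equal(length(st$failures), 0L)

  # ten reconstructions per sample: full-data reference + 3 algorithms x 3
  # reduction levels
  perSample <- table(paste(st$samples$group, st$samples$sample))
  expect_true(all(perSample == 10))
  expect_setequal(unique(st$samples$algorithm), c("fdk", "cgls", "tv", "dart"))
  expect_setequal(unique(st$samples$level), c("full", "1/2", "1/4", "1/6"))

  # six parameters per cell
  params <- c("bvtv", "tbth", "tbs", "tbn", "ef", "plth")
  expect_true(all(params %in% names(st$samples)))
  expect_equal(nrow(st$descriptives), 10 * 6)

  # every iterative cell has a relative-error summary; the reference has none
  expect_equal(nrow(st$relerr), 9 * 6)
  expect_true(all(st$relerr$meanRelErr >= 0))

  # end-to-end determinism under the master seed
  st2 <- suppressWarnings(runStudy(cfg, verbose = FALSE))
  expect_identical(st$samples, st2$samples)
  expect_identical(st$descriptives, st2$descriptives)
})

test_that("study reports round-trip and use the printed p-value convention", {
  cfg <- studyConfig("smoke", masterSeed = 4L, nAclt = 2L, nControl = 2L)
  st <- suppressWarnings(runStudy(cfg, verbose = FALSE))
  dir <- file.path(tempdir(), "studyout")
  paths <- reportStudy(st, dir, formats = c("csv", "json"))
  expect_true(file.exists(file.path(dir, "descriptives.csv")))
  expect_true(file.exists(file.path(dir, "study.json")))
  expect_true(file.exists(file.path(dir, "manifest.json")))

  desc <- read.csv(file.path(dir, "descriptives.csv"))
  # "one-tailed (two-tailed)" formatting
  expect_true(all(grepl("^[0-9.]+ \\([0-9.]+\\)$", desc$p)))
  # round trip: numeric cells re-parse identically
  expect_equal(desc$acltMean, st$descriptives$acltMean)
  expect_equal(desc$pTwo, st$descriptives$pTwo)
  # every algorithm/level/parameter cell is present
  expect_equal(nrow(desc), 10 * 6)

  samp <- read.csv(file.path(dir, "samples.csv"))
  expect_equal(nrow(samp), nrow(st$samples))
})
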