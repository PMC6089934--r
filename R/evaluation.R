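#' @include cohort.R cgls.R tv.R dart.R fbp.R segmentation.R morphometry.R stats.R
NULL

paramNames <- c("bvtv", "tbth", "tbs", "tbn", "ef", "plth")

#' Study configuration
#'
#' Assembles the full evaluation study: two cohorts (destabilized ACLT and
#' control), a short-scan fan-beam geometry, the reconstruction grid
#' (full-data FBP reference plus CGLS / TV / DART at one-half, one-quarter
#' and one-sixth of the views -- ten reconstructions per sample), the
#' segmentation configuration, and every derived random seed.
#'
#' Presets: "demo" is the desk-scale default study (256 x 256 single-slice
#' samples, 6 + 6 samples, 260 views at 0.7 degrees); "smoke" is a fast
#' end-to-end check (96 x 96 slices, 2 + 2 samples, 120 views at 1.51
#' degrees).
#'
#' @param preset "demo" or "smoke".
#' @param masterSeed master seed; every stage seed derives from it.
#' @param nAclt,nControl cohort sizes (preset defaults: 6 + 6 or 2 + 2).
#' @param i0 incident photons per detector element (default 30000).
#' @param frames frames averaged per projection (default 2).
#' @return a list of class "tomomorphStudyConfig".
#' @export
studyConfig <- function(preset = c("demo", "smoke"), masterSeed = 1L,
                        nAclt = NULL, nControl = NULL, i0 = 3e4, frames = 2L) {
  preset <- match.arg(preset)
  if (preset == "demo") {
    nSlice <- 256L
    nAngles <- 260L; stepDeg <- 0.7
    if (is.null(nAclt)) nAclt <- 6L
    if (is.null(nControl)) nControl <- 6L
    efSeeds <- 120L
  } else {
    nSlice <- 96L
    nAngles <- 120L; stepDeg <- 1.51
    if (is.null(nAclt)) nAclt <- 2L
    if (is.null(nControl)) nControl <- 2L
    efSeeds <- 60L
  }
  structure(list(
    preset = preset, masterSeed = as.integer(masterSeed),
    nSlice = nSlice, nAngles = nAngles, stepDeg = stepDeg,
    sad = 400, sdd = 800, detCount = as.integer(ceiling(1.4 * nSlice)),
    i0 = i0, frames = as.integer(frames), reductions = c(2L, 4L, 6L),
    nAclt = as.integer(nAclt), nControl = as.integer(nControl),
    segConfig = SegmentationConfig(despeckleMode = "min-size"),
    efSeeds = efSeeds, efExtrude = 4L,
    grayValues = c(0, 0.038, 0.18), nIter = 25L,
    lambdaPoints = 8L), class = "tomomorphStudyConfig")
}

# Deterministic CNR ROIs from the ground truth: a pure-bone patch inside the
# plate band and a background patch in the volume corner (both >= 25 voxels).
cnrRois <- function(truth) {
  labels <- phantomLabels(truth)
  d <- dim(labels)
  plate <- regionMasks(truth)$plate
  boneIn <- (labels == 2L) & plate
  er <- boneIn & erodeBall(boneIn, 2)
  if (sum(er) < 25) er <- boneIn
  if (sum(er) > 400) {                      # cap the ROI size, keep determinism
    idx <- which(er)
    er[] <- FALSE
    er[idx[seq_len(400)]] <- TRUE
  }
  bg <- maskLike(plate, FALSE)
  bg[3:14, 3:14, ] <- TRUE
  bg <- bg & (labels == 0L)
  list(bone = er, background = bg)
}

levelLabel <- function(k) {
  if (k == 1L) "full" else sprintf("1/%d", k)
}

#' Run the full evaluation study
#'
#' For every sample of both cohorts: generate the phantom, forward-project
#' with the short-scan fan-beam geometry, add Poisson noise, reconstruct the
#' full data with FBP (the reference) and each reduced view set (one-half,
#' one-quarter, one-sixth) with CGLS, TV and DART, segment every
#' reconstruction with the Otsu chain, and compute the six morphometric
#' parameters plus CNR. The TV weight is chosen once per sparsity level by
#' the L-curve method on a pilot sample and reused across samples. Group
#' descriptives, exact Mann-Whitney p-values, relative errors against the
#' per-sample full-data FBP reference, and CNR summaries are tabulated. The
#' whole study is deterministic under the master seed.
#'
#' @param config a configuration from [studyConfig()].
#' @param verbose print per-sample progress.
#' @return list of class "tomomorphStudy": samples (per-sample parameter
#'   table), descriptives (group mean/SD + p-values per cell), relerr
#'   (relative-error summaries vs the reference), cnr (CNR summaries),
#'   significance (two-tailed p < 0.05 marks), lambdas, failures, config.
#' @export
runStudy <- function(config = studyConfig(), verbose = interactive()) {
  ms <- config$masterSeed
  cohorts <- list(
    aclt = sampleCohort(CohortSpec("aclt", n = config$nAclt,
                                   baseSeed = deriveSeed(ms, 1L),
                                   mode = "slice2d",
                                   gridShape = c(config$nSlice, config$nSlice, 1L)),
                        grayValues = config$grayValues),
    control = sampleCohort(CohortSpec("control", n = config$nControl,
                                      baseSeed = deriveSeed(ms, 2L),
                                      mode = "slice2d",
                                      gridShape = c(config$nSlice, config$nSlice, 1L)),
                           grayValues = config$grayValues))

  # the sample is confined to the inscribed disc, which the detector covers;
  # the shadow warning applies to the (empty) square corners only
  geomFull <- suppressWarnings(
    buildGeometry("fan2d", nAngles = config$nAngles,
                  stepDeg = config$stepDeg,
                  detCount = config$detCount,
                  sad = config$sad, sdd = config$sdd,
                  lattice = cohorts$aclt[[1]]$volume))
  prior <- GrayPrior(config$grayValues)

  # pilot L-curve lambda per reduction level (first ACLT sample)
  pilotSino <- addNoise(forwardProject(cohorts$aclt[[1]]$volume, geomFull),
                        config$i0, config$frames, seed = deriveSeed(ms, 90L))
  lambdas <- setNames(numeric(length(config$reductions)),
                      as.character(config$reductions))
  for (k in config$reductions) {
    sub <- subsampleProjections(pilotSino, k)
    op <- tomoOperator(geometry(sub))
    grid <- defaultLambdaGrid(sub, op, nPoints = config$lambdaPoints)
    # the pilot solves run longer than the study reconstructions so the
    # L-curve is traced on converged points
    sel <- selectLambdaTV(sub, op, grid,
                          ReconConfig("tv", nIter = 4L * config$nIter))
    lambdas[as.character(k)] <- sel$lambda
    if (verbose) message(sprintf("pilot lambda (1/%d views): %.3g", k,
                                 sel$lambda))
  }

  rows <- list()
  failures <- list()
  sampleNo <- 0L
  for (grp in names(cohorts)) {
    for (i in seq_along(cohorts[[grp]])) {
      sampleNo <- sampleNo + 1L
      ph <- cohorts[[grp]][[i]]
      res <- tryCatch({
        studyOneSample(ph, grp, i, sampleNo, geomFull, prior, lambdas, config)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[[sprintf("%s_%d", grp, i)]] <- conditionMessage(res)
        next
      }
      rows[[sampleNo]] <- res
      if (verbose) message(sprintf("sample %s %d done", grp, i))
    }
  }
  samples <- do.call(rbind, rows)
  out <- list(samples = samples,
              descriptives = studyDescriptives(samples),
              relerr = studyRelErr(samples),
              cnr = studyCnr(samples),
              lambdas = lambdas, failures = failures, config = config)
  out$significance <- studySignificance(out$descriptives)
  class(out) <- "tomomorphStudy"
  out
}

# One sample: all ten reconstructions -> one data.frame block.
studyOneSample <- function(ph, grp, i, sampleNo, geomFull, prior, lambdas,
                           config) {
  ms <- config$masterSeed
  sino <- addNoise(forwardProject(ph$volume, geomFull), config$i0,
                   config$frames, seed = deriveSeed(ms, 100L + sampleNo))
  regions <- regionMasks(ph$truth)
  voi <- regions$trabecular
  rois <- cnrRois(ph$truth)
  efSeed <- deriveSeed(ms, 500L + sampleNo)

  evalRecon <- function(vol, algorithm, k) {
    masks <- segmentBone(vol, regions, config$segConfig)
    m <- computeMorphometry(masks$trabecular, masks$plate, voi,
                            voxelSize(vol), efSeeds = config$efSeeds,
                            efSeed = efSeed, efExtrude = config$efExtrude)
    cn <- computeCNR(vol, rois$bone, rois$background)
    cbind(data.frame(group = grp, sample = i, algorithm = algorithm,
                     level = levelLabel(k), stringsAsFactors = FALSE),
          as.data.frame(m), data.frame(cnr = cn))
  }

  out <- list(evalRecon(reconstructFDK(sino), "fdk", 1L))
  for (k in config$reductions) {
    sub <- subsampleProjections(sino, k)
    op <- tomoOperator(geometry(sub))
    out <- c(out, list(
      evalRecon(reconstructCGLS(sub, op, ReconConfig("cgls", nIter = config$nIter)),
                "cgls", k),
      evalRecon(reconstructTV(sub, op,
                              ReconConfig("tv", nIter = config$nIter,
                                          tvLambda = lambdas[as.character(k)])),
                "tv", k),
      evalRecon(reconstructDART(sub, op, prior,
                                ReconConfig("dart", nIter = config$nIter,
                                            seed = deriveSeed(ms, 900L + sampleNo))),
                "dart", k)))
  }
  do.call(rbind, out)
}

# Group descriptives and exact Mann-Whitney p-values per cell and parameter.
studyDescriptives <- function(samples) {
  cells <- unique(samples[, c("algorithm", "level")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    sub <- samples[samples$algorithm == cells$algorithm[r] &
                   samples$level == cells$level[r], ]
    for (p in paramNames) {
      a <- sub[[p]][sub$group == "aclt"]
      b <- sub[[p]][sub$group == "control"]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      tst <- if (length(a) >= 1 && length(b) >= 1)
        mannWhitneyExact(a, b) else NULL
      out[[length(out) + 1L]] <- data.frame(
        algorithm = cells$algorithm[r], level = cells$level[r], parameter = p,
        acltMean = mean(a), acltSd = stats::sd(a),
        controlMean = mean(b), controlSd = stats::sd(b),
        pOne = if (is.null(tst)) NA_real_ else tst@pOne,
        pTwo = if (is.null(tst)) NA_real_ else tst@pTwo,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Relative errors against a reference
#'
#' Per-sample relative error |value - reference| / |reference| * 100 (%),
#' with zero-reference samples excluded with a warning, and the mean / SD
#' aggregate.
#'
#' @param values numeric vector of per-sample values.
#' @param reference numeric vector of the per-sample reference values.
#' @return list(perSample, mean, sd, nExcluded).
#' @examples
#' relativeErrors(c(220, 180), c(200, 200))$perSample  # 10 10
#' @export
relativeErrors <- function(values, reference) {
  stopifnot(length(values) == length(reference))
  ok <- is.finite(values) & is.finite(reference) & reference != 0
  nEx <- sum(is.finite(values) & is.finite(reference) & reference == 0)
  if (nEx > 0)
    warning(sprintf("%d sample(s) with zero reference excluded", nEx))
  pe <- abs(values[ok] - reference[ok]) / abs(reference[ok]) * 100
  list(perSample = pe, mean = mean(pe), sd = stats::sd(pe), nExcluded = nEx)
}

# Relative-error summary of every iterative cell against per-sample FDK full.
studyRelErr <- function(samples) {
  ref <- samples[samples$algorithm == "fdk", ]
  key <- function(d) paste(d$group, d$sample)
  out <- list()
  cells <- unique(samples[samples$algorithm != "fdk", c("algorithm", "level")])
  for (r in seq_len(nrow(cells))) {
    sub <- samples[samples$algorithm == cells$algorithm[r] &
                   samples$level == cells$level[r], ]
    m <- match(key(sub), key(ref))
    for (p in paramNames) {
      re <- suppressWarnings(relativeErrors(sub[[p]], ref[[p]][m]))
      out[[length(out) + 1L]] <- data.frame(
        algorithm = cells$algorithm[r], level = cells$level[r], parameter = p,
        meanRelErr = re$mean, sdRelErr = re$sd, n = length(re$perSample),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

studyCnr <- function(samples) {
  cells <- unique(samples[, c("algorithm", "level")])
  out <- list()
  for (r in seq_len(nrow(cells))) {
    v <- samples$cnr[samples$algorithm == cells$algorithm[r] &
                     samples$level == cells$level[r]]
    fin <- v[is.finite(v)]
    out[[length(out) + 1L]] <- data.frame(
      algorithm = cells$algorithm[r], level = cells$level[r],
      cnrMean = if (length(fin)) mean(fin) else NA_real_,
      cnrSd = if (length(fin) > 1) stats::sd(fin) else NA_real_,
      nUndefined = sum(!is.finite(v)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Which parameters keep a significant (two-tailed p < 0.05) group difference.
studySignificance <- function(desc) {
  data.frame(algorithm = desc$algorithm, level = desc$level,
             parameter = desc$parameter,
             significantTwoTailed = !is.na(desc$pTwo) & desc$pTwo < 0.05,
             stringsAsFactors = FALSE)
}

#' @export
print.tomomorphStudy <- function(x, ...) {
  cat(sprintf("tomomorph study (%s): %d sample rows, %d failures\n",
              x$config$preset, nrow(x$samples), length(x$failures)))
  invisible(x)
}

#' Write study tables to files
#'
#' CSV tables (descriptives with p-values formatted "one-tailed (two-tailed)",
#' relative errors, CNR, per-sample values), a JSON dump of everything, a run
#' manifest, and optional PNG plots of relative error and CNR against the
#' number of projections.
#'
#' @param study result of [runStudy()].
#' @param dir output directory (created if missing).
#' @param formats subset of c("csv", "json", "png").
#' @return invisible vector of written paths.
#' @export
reportStudy <- function(study, dir, formats = c("csv", "json")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  desc <- study$descriptives
  desc$p <- sprintf("%.3f (%.3f)", desc$pOne, desc$pTwo)
  if ("csv" %in% formats) {
    for (nm in c("descriptives", "relerr", "cnr", "samples", "significance")) {
      f <- file.path(dir, paste0(nm, ".csv"))
      tab <- if (nm == "descriptives") desc else study[[nm]]
      utils::write.csv(tab, f, row.names = FALSE)
      paths <- c(paths, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "study.json")
    jsonlite::write_json(
      list(descriptives = desc, relerr = study$relerr, cnr = study$cnr,
           significance = study$significance, lambdas = as.list(study$lambdas),
           failures = study$failures,
           config = study$config[setdiff(names(study$config), "segConfig")]),
      f, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    paths <- c(paths, f)
  }
  if ("png" %in% formats) {
    f <- file.path(dir, "relative_errors.png")
    grDevices::png(f, width = 900, height = 600)
    plotRelErr(study)
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  mf <- file.path(dir, "manifest.json")
  writeManifest(mf, config = study$config,
                seeds = list(master = study$config$masterSeed),
                files = paths)
  invisible(c(paths, mf))
}

# Base-graphics bar chart of mean relative error per algorithm/level.
plotRelErr <- function(study) {
  re <- study$relerr
  algs <- unique(re$algorithm)
  levs <- unique(re$level)
  means <- sapply(levs, function(l) sapply(algs, function(a)
    mean(re$meanRelErr[re$algorithm == a & re$level == l], na.rm = TRUE)))
  graphics::barplot(means, beside = TRUE, legend.text = algs,
                    xlab = "fraction of full projection data",
                    ylab = "mean relative error vs reference (%)")
}
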