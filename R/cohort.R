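#' @include phantoms.R
NULL

#' Reference group statistics for cohort calibration
#'
#' The per-group calibration targets (mean, SD) used by the synthetic cohorts:
#' bone volume fraction (%), trabecular thickness (um), trabecular separation
#' (um) and subchondral plate thickness (um) of the surgically destabilized
#' (ACLT, anterior cruciate ligament transection) and unoperated control
#' groups, as measured on the full-data reference reconstructions of the
#' rabbit osteoarthritis model this pipeline emulates.
#'
#' @param group "aclt" or "control".
#' @return named list of c(mean, sd) per parameter.
#' @examples
#' groupTargets("aclt")$bvtv  # c(47.7, 4.4)
#' @export
groupTargets <- function(group = c("aclt", "control")) {
  group <- match.arg(group)
  if (group == "aclt")
    list(bvtv = c(47.7, 4.4), tbth = c(202.9, 18.2),
         tbs = c(311.6, 45.0), plth = c(531.8, 90.7))
  else
    list(bvtv = c(51.9, 3.4), tbth = c(214.7, 16.1),
         tbs = c(285.6, 25.9), plth = c(485.0, 99.7))
}

#' Create a cohort specification
#'
#' @param group "aclt" or "control".
#' @param n number of samples (defaults: 12 for ACLT, 16 for control).
#' @param targets per-parameter c(mean, sd) list; defaults to
#'   [groupTargets()].
#' @param baseSeed base random seed.
#' @param mode "voi3d" (default: an 80 x 80 x 160 voxel volume of interest)
#'   or "slice2d" (a 256 x 256 single-slice disc sample with a plate band).
#' @param gridShape voxel counts; defaults depend on `mode`.
#' @return A [CohortSpec-class].
#' @export
CohortSpec <- function(group = c("aclt", "control"), n = NULL,
                       targets = groupTargets(group), baseSeed = 1L,
                       mode = c("voi3d", "slice2d"), gridShape = NULL) {
  group <- match.arg(group)
  mode <- match.arg(mode)
  if (is.null(n)) n <- if (group == "aclt") 12L else 16L
  if (is.null(gridShape))
    gridShape <- if (mode == "voi3d") c(80L, 80L, 160L) else c(256L, 256L, 1L)
  if (length(gridShape) == 2L) gridShape <- c(gridShape, 1L)
  new("CohortSpec", group = group, n = as.integer(n), targets = targets,
      baseSeed = as.integer(baseSeed), mode = mode,
      gridShape = as.integer(gridShape))
}

# Calibration table: measured (Tb.Th, Tb.S) of thresholded Gaussian-field
# phantoms as a function of correlation length and BV/TV, per mode. Shipped
# with the package (built once by the sweep in inst/scripts).
calibrationTable <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "trabecular_calibration.csv",
                          package = "tomomorph")
      if (!nzchar(path)) stop("calibration table not found")
      cache <<- utils::read.csv(path)
    }
    cache
  }
})

#' Correlation length for a trabecular thickness target
#'
#' Inverts the shipped calibration table (measured Tb.Th of thresholded
#' Gaussian-field phantoms over a grid of correlation lengths and volume
#' fractions) by bilinear interpolation; values outside the calibrated range
#' are clamped with a warning.
#'
#' @param tbthUm target trabecular thickness (um).
#' @param bvtvPct target bone volume fraction (percent).
#' @param mode "voi3d" or "slice2d" (the two calibrated generator modes).
#' @return correlation length in um.
#' @export
calibrateCorrLength <- function(tbthUm, bvtvPct, mode = "voi3d") {
  tab <- calibrationTable()
  tab <- tab[tab$mode == mode, ]
  if (nrow(tab) == 0) stop("no calibration entries for mode ", mode)
  bvs <- sort(unique(tab$bvtv_pct))
  bv <- min(max(bvtvPct, min(bvs)), max(bvs))
  # interpolate measured tbth over bvtv at each correlation length
  lens <- sort(unique(tab$corr_len_um))
  thAt <- vapply(lens, function(L) {
    sub <- tab[tab$corr_len_um == L, ]
    stats::approx(sub$bvtv_pct, sub$tbth_um, xout = bv, rule = 2)$y
  }, 0)
  if (tbthUm <= min(thAt) || tbthUm >= max(thAt)) {
    if (tbthUm < min(thAt) - 10 || tbthUm > max(thAt) + 10)
      warning(sprintf(
        "Tb.Th target %.1f um outside the calibrated range [%.1f, %.1f]; clamped",
        tbthUm, min(thAt), max(thAt)))
    return(lens[which.min(abs(thAt - tbthUm))])
  }
  stats::approx(thAt, lens, xout = tbthUm, rule = 2, ties = "ordered")$y
}

#' Sample a synthetic cohort
#'
#' Draws per-sample parameter targets from normal distributions at the
#' group's mean and SD -- with the draws standardized so the realized sample
#' mean and SD match the targets exactly (the cohort emulates the printed
#' group statistics, not sampling variability on top of them) -- truncated to
#' plus/minus 3 SD and physical bounds, maps the Tb.Th target to a
#' correlation length through the calibration table, and generates one
#' trabecular phantom per sample. Deterministic under `baseSeed`.
#'
#' @param cohort a [CohortSpec-class].
#' @param grayValues attenuation triple passed to the phantoms.
#' @return list of list(volume, truth) of length `cohort@n`.
#' @export
sampleCohort <- function(cohort, grayValues = c(0, 0.038, 0.18)) {
  validObject(cohort)
  n <- cohort@n
  pars <- c("bvtv", "tbth", "tbs", "plth")
  z <- withSeed(cohort@baseSeed, matrix(rnorm(n * length(pars)), n))
  if (n >= 2L)
    z <- scale(z)                 # exact moment matching: mean 0, SD 1
  else z <- matrix(0, n, length(pars))
  z <- pmin(pmax(z, -3), 3)
  draws <- vapply(seq_along(pars), function(j) {
    t <- cohort@targets[[pars[j]]]
    t[1] + t[2] * z[, j]
  }, numeric(n))
  draws <- matrix(draws, nrow = n, dimnames = list(NULL, pars))
  vs <- 25
  draws[, "bvtv"] <- pmin(pmax(draws[, "bvtv"], 5), 95)
  draws[, "tbth"] <- pmax(draws[, "tbth"], 3 * vs)
  draws[, "plth"] <- pmax(draws[, "plth"], 4 * vs)

  lapply(seq_len(n), function(i) {
    corr <- calibrateCorrLength(draws[i, "tbth"], draws[i, "bvtv"],
                                cohort@mode)
    spec <- PhantomSpec(
      gridShape = cohort@gridShape, voxelSize = vs, grayValues = grayValues,
      structure = "trabecular",
      structureParams = list(
        bvtv = draws[i, "bvtv"], corrLength = corr,
        region = if (cohort@mode == "slice2d") "disc" else "full"),
      plateLayer = if (cohort@mode == "slice2d")
        list(thickness = draws[i, "plth"], poreFraction = 0.05) else list(),
      seed = deriveSeed(cohort@baseSeed, i))
    ph <- makeTrabecularPhantom(spec)
    ph$truth@morphometry$drawnTargets <- as.list(draws[i, ])
    ph
  })
}
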