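#' @include projector.R
NULL

# Forward differences with replicated (Neumann) far border, per axis.
gradAxis <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  if (n == 1L) return(array(0, dim = d))
  idx <- c(seq(2L, n), n)
  g <- switch(axis,
              u[idx, , , drop = FALSE] - u,
              u[, idx, , drop = FALSE] - u,
              u[, , idx, drop = FALSE] - u)
  array(g, dim = d)
}

# Negative adjoint of gradAxis (discrete divergence contribution).
divAxis <- function(g, axis) {
  d <- dim(g)
  n <- d[axis]
  if (n == 1L) return(array(0, dim = d))
  out <- array(0, dim = d)
  take <- function(x, i) switch(axis, x[i, , , drop = FALSE],
                                x[, i, , drop = FALSE], x[, , i, drop = FALSE])
  assignAxis <- function(x, i, v) {
    switch(axis, x[i, , ] <- v, x[, i, ] <- v, x[, , i] <- v)
    x
  }
  # adjoint of (shift - identity) with replicated border
  first <- take(g, 1L)
  out <- assignAxis(out, 1L, -first)
  if (n > 2L) {
    mid <- take(g, seq(1L, n - 2L)) - take(g, seq(2L, n - 1L))
    out <- assignAxis(out, seq(2L, n - 1L), mid)
  }
  lastIn <- take(g, n - 1L)
  out <- assignAxis(out, n, lastIn)
  out
}

# Smoothed total variation and its gradient.
tvValueGrad <- function(u, eps) {
  gx <- gradAxis(u, 1L); gy <- gradAxis(u, 2L); gz <- gradAxis(u, 3L)
  mag <- sqrt(gx^2 + gy^2 + gz^2 + eps^2)
  val <- sum(mag)
  grad <- divAxis(gx / mag, 1L) + divAxis(gy / mag, 2L) + divAxis(gz / mag, 3L)
  list(value = val, grad = grad)
}

#' Total variation of a volume
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient
#' (unsmoothed, eps = 0). Used for reporting and the L-curve penalty axis.
#'
#' @param volume a [VoxelVolume-class] or array.
#' @return scalar TV value.
#' @export
totalVariation <- function(volume) {
  u <- if (is(volume, "VoxelVolume")) volume@data else as3d(volume)
  gx <- gradAxis(u, 1L); gy <- gradAxis(u, 2L); gz <- gradAxis(u, 3L)
  sum(sqrt(gx^2 + gy^2 + gz^2))
}

#' TV-regularized reconstruction with Barzilai-Borwein steps
#'
#' Minimizes F(u) = 1/2 ||A u - b||^2 + lambda * sum(sqrt(|grad u|^2 + eps^2))
#' by gradient descent with the Barzilai-Borwein (BB1) step length
#' s's / s'y, safeguarded into [1e-8, 1e8] and falling back to the initial
#' exact line-search step when the curvature estimate is non-positive. Runs
#' `nIter` (default 25) steps from the zero image.
#'
#' @param projections a [ProjectionSet-class].
#' @param operator a [TomoOperator-class]; defaults to the geometry operator.
#' @param config a [ReconConfig-class]: `tvLambda`, `tvEpsilon` (NA gives
#'   1e-4 times the 99.9th percentile of a backprojection-scaled data proxy),
#'   `nIter`.
#' @return A [VoxelVolume-class] with attribute "objective" (per-iteration
#'   objective values, starting value first).
#' @export
reconstructTV <- function(projections, operator = NULL,
                          config = ReconConfig("tv")) {
  g <- geometry(projections)
  if (is.null(operator)) operator <- tomoOperator(g)
  b <- as.double(projData(projections))
  if (any(!is.finite(b))) stop("projection data contains non-finite values")
  lambda <- config@tvLambda
  eps <- config@tvEpsilon
  A <- function(x) as.double(operator@forward(x))
  At <- function(y) as.double(operator@adjoint(y))
  volDim <- operator@volDim
  n <- prod(volDim)

  if (is.na(eps)) {
    # scale-aware smoothing constant from a single CGLS-like step
    g0 <- At(b)
    eps <- 1e-4 * max(abs(g0)) * sum(g0 * g0) / max(sum(A(g0)^2),
                                                    .Machine$double.xmin)
    if (!is.finite(eps) || eps <= 0) eps <- 1e-8
  }
  if (eps <= 0) stop("tvEpsilon must be positive")

  objective <- function(u, Au) {
    tv <- tvValueGrad(array(u, dim = volDim), eps)
    0.5 * sum((Au - b)^2) + lambda * tv$value
  }
  gradient <- function(u, Au) {
    tv <- tvValueGrad(array(u, dim = volDim), eps)
    At(Au - b) + lambda * as.double(tv$grad)
  }

  u <- numeric(n)
  Au <- A(u)
  obj <- numeric(config@nIter + 1)
  obj[1] <- objective(u, Au)
  grd <- gradient(u, Au)
  # exact line search step for the quadratic part as initial/fallback step
  Ag <- A(grd)
  alpha0 <- sum(grd * grd) / max(sum(Ag * Ag), .Machine$double.xmin)
  alpha <- alpha0
  best <- list(u = u, Au = Au, obj = obj[1])
  for (it in seq_len(config@nIter)) {
    # nonmonotone (5-step memory) backtracking keeps the BB step from
    # diverging on strongly regularized problems
    ref <- max(obj[max(1L, it - 4L):it])
    tries <- 0L
    repeat {
      uNew <- u - alpha * grd
      AuNew <- A(uNew)
      objNew <- objective(uNew, AuNew)
      if (objNew <= ref || tries >= 12L) break
      alpha <- alpha / 2
      tries <- tries + 1L
    }
    grdNew <- gradient(uNew, AuNew)
    s <- uNew - u
    y <- grdNew - grd
    sy <- sum(s * y)
    alpha <- if (sy > 0) sum(s * s) / sy else alpha0
    alpha <- min(max(alpha, 1e-8), 1e8)
    u <- uNew; Au <- AuNew; grd <- grdNew
    obj[it + 1L] <- objNew
    if (objNew < best$obj) best <- list(u = u, Au = Au, obj = objNew)
  }
  # report the best iterate: final objective never exceeds the initial one
  out <- VoxelVolume(array(best$u, dim = volDim), g@voxelSize)
  attr(out, "objective") <- obj
  attr(out, "residualNorm") <- sqrt(sum((best$Au - b)^2))
  attr(out, "tvEpsilon") <- eps
  out
}

#' L-curve corner by discrete Menger curvature
#'
#' Given per-lambda residual norms and penalty values, forms the log-log
#' L-curve and returns the lambda of maximum three-point (Menger) curvature;
#' collinear points have zero curvature and ties resolve to the smaller
#' lambda.
#'
#' @param lambdas positive, sorted regularization weights.
#' @param residuals residual norms ||A u - b|| per lambda.
#' @param penalties penalty values TV(u) per lambda.
#' @return list(lambda, curvatures).
#' @export
lcurveCorner <- function(lambdas, residuals, penalties) {
  m <- length(lambdas)
  if (m < 3L) {
    warning("fewer than 3 L-curve points; returning the first lambda")
    return(list(lambda = lambdas[1], curvatures = rep(0, m)))
  }
  x <- log(pmax(residuals, .Machine$double.xmin))
  y <- log(pmax(penalties, .Machine$double.xmin))
  curv <- rep(0, m)
  for (i in 2:(m - 1)) {
    p1 <- c(x[i - 1], y[i - 1]); p2 <- c(x[i], y[i]); p3 <- c(x[i + 1], y[i + 1])
    a <- sqrt(sum((p2 - p1)^2)); bb <- sqrt(sum((p3 - p2)^2))
    cc <- sqrt(sum((p3 - p1)^2))
    cross <- (p2[1] - p1[1]) * (p3[2] - p1[2]) -
             (p2[2] - p1[2]) * (p3[1] - p1[1])
    denom <- a * bb * cc
    curv[i] <- if (denom > 0) 2 * abs(cross) / denom else 0
  }
  best <- which(curv == max(curv))[1]   # ties -> smallest lambda (sorted input)
  if (max(curv) == 0) best <- 1L
  list(lambda = lambdas[best], curvatures = curv)
}

#' Select the TV weight with the L-curve method
#'
#' Runs [reconstructTV()] for every lambda on the grid, records the residual
#' norm and the (unsmoothed) total variation, and picks the corner of the
#' log-log curve via [lcurveCorner()].
#'
#' @param projections a [ProjectionSet-class].
#' @param operator a [TomoOperator-class] or NULL.
#' @param lambdaGrid positive, sorted grid (>= 3 values recommended; fewer
#'   fall back with a warning).
#' @param config base [ReconConfig-class] for the per-lambda solves.
#' @return list(lambda, table) where table has lambda / residual / penalty /
#'   curvature columns.
#' @export
selectLambdaTV <- function(projections, operator = NULL, lambdaGrid,
                           config = ReconConfig("tv")) {
  stopifnot(all(lambdaGrid > 0), !is.unsorted(lambdaGrid))
  res <- pen <- numeric(length(lambdaGrid))
  for (i in seq_along(lambdaGrid)) {
    cfg <- config
    cfg@tvLambda <- lambdaGrid[i]
    u <- reconstructTV(projections, operator, cfg)
    res[i] <- attr(u, "residualNorm")
    pen[i] <- totalVariation(u)
  }
  corner <- lcurveCorner(lambdaGrid, res, pen)
  list(lambda = corner$lambda,
       table = data.frame(lambda = lambdaGrid, residual = res, penalty = pen,
                          curvature = corner$curvatures))
}

#' Default logarithmic lambda grid for the L-curve
#'
#' Eight points bracketing the weight at which the data-misfit and penalty
#' gradients balance on a one-step pilot estimate.
#'
#' @param projections a [ProjectionSet-class].
#' @param operator a [TomoOperator-class] or NULL.
#' @param nPoints number of grid points (default 8).
#' @return numeric vector of lambdas, sorted.
#' @export
defaultLambdaGrid <- function(projections, operator = NULL, nPoints = 8L) {
  g <- geometry(projections)
  if (is.null(operator)) operator <- tomoOperator(g)
  g0 <- as.double(operator@adjoint(as.double(projData(projections))))
  lam0 <- stats::quantile(abs(g0), 0.999) + .Machine$double.xmin
  lam0 * 10^seq(-4.5, -0.5, length.out = nPoints)
}
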