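#' @include projector.R
NULL

# Core CGLS on a generic linear operator given as forward/adjoint closures.
# Solves min ||A x - b|| by conjugate gradients on the normal equations,
# starting from x0 (zero by default). Returns list(x, residuals) where
# residuals[i] = ||A x_i - b|| after iteration i (residuals[1] is the start).
cglsCore <- function(forward, adjoint, b, x0, nIter) {
  x <- x0
  r <- b - forward(x)
  s <- adjoint(r)
  p <- s
  gamma <- sum(s * s)
  resid <- sqrt(sum(r * r))
  hist <- numeric(nIter + 1)
  hist[1] <- resid
  for (it in seq_len(nIter)) {
    if (gamma <= .Machine$double.xmin) {
      hist[it + 1L] <- hist[it]
      next
    }
    q <- forward(p)
    qq <- sum(q * q)
    if (qq <= .Machine$double.xmin) {
      hist[it + 1L] <- hist[it]
      next
    }
    alpha <- gamma / qq
    x <- x + alpha * p
    r <- r - alpha * q
    s <- adjoint(r)
    gammaNew <- sum(s * s)
    p <- s + (gammaNew / gamma) * p
    gamma <- gammaNew
    hist[it + 1L] <- sqrt(sum(r * r))
  }
  list(x = x, residuals = hist)
}

#' CGLS reconstruction
#'
#' Conjugate gradients on the least-squares normal equations, started from the
#' zero image; returns the iterate after `nIter` (default 25) iterations. The
#' per-iteration residual norms are attached as attribute "residuals".
#'
#' @param projections a [ProjectionSet-class].
#' @param operator a [TomoOperator-class]; defaults to the projection set's
#'   geometry operator.
#' @param config a [ReconConfig-class] (`nIter`).
#' @return A [VoxelVolume-class] with attribute "residuals".
#' @export
reconstructCGLS <- function(projections, operator = NULL,
                            config = ReconConfig("cgls")) {
  g <- geometry(projections)
  if (is.null(operator)) operator <- tomoOperator(g)
  b <- as.double(projData(projections))
  if (any(!is.finite(b))) stop("projection data contains non-finite values")
  fit <- cglsCore(function(x) as.double(operator@forward(x)),
                  function(y) as.double(operator@adjoint(y)),
                  b, numeric(prod(operator@volDim)), config@nIter)
  out <- VoxelVolume(array(fit$x, dim = operator@volDim), g@voxelSize)
  attr(out, "residuals") <- fit$residuals
  out
}
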