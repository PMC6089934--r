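#' @include projector.R
NULL

#' Apodized ramp filter frequency response
#'
#' The ideal ramp response |f| multiplied by the Hamming window
#' W(f) = alpha + (1 - alpha) cos(pi f / fN). The response is zero at f = 0
#' (the ramp removes the DC component).
#'
#' @param freqFrac frequency as a fraction of the Nyquist frequency, in [0, 1].
#' @param alpha Hamming window parameter (default 0.54).
#' @return the filter response (same scale as freqFrac).
#' @examples
#' rampFilterResponse(0)    # 0
#' rampFilterResponse(1, 0.54)
#' @export
rampFilterResponse <- function(freqFrac, alpha = 0.54) {
  freqFrac * (alpha + (1 - alpha) * cos(pi * freqFrac))
}

# Ramp-filter a (detector x angle) sinogram. Uses the band-limited ramp
# (Ram-Lak) spatial kernel, apodized by the Hamming window in the frequency
# domain. `pitch` is the detector sample spacing in mm (isocenter scale).
# Returns the filtered sinogram, same shape.
rampFilter <- function(sino, pitch, alpha = 0.54) {
  nd <- nrow(sino)
  nfft <- 2^ceiling(log2(2 * nd))
  # discrete ramp kernel h (units 1/pitch^2), circularly arranged
  k <- c(0:(nfft / 2), (-nfft / 2 + 1):-1)
  h <- numeric(nfft)
  h[1] <- 1 / 4
  odd <- which(k %% 2 != 0)
  h[odd] <- -1 / (pi^2 * k[odd]^2)
  H <- Re(fft(h))
  frac <- pmin(abs(k), nfft / 2) / (nfft / 2)
  W <- alpha + (1 - alpha) * cos(pi * frac)
  HW <- H * W
  pad <- rbind(sino, matrix(0, nfft - nd, ncol(sino)))
  filt <- Re(stats::mvfft(stats::mvfft(pad) * HW, inverse = TRUE)) / nfft
  filt[seq_len(nd), , drop = FALSE] / pitch
}

# Parker short-scan weights for a flat-detector fan beam. `gammas` are the
# per-element fan angles (radians), `betas` the view angles (radians, shifted
# to start at 0), `Gamma` the half over-scan (span - pi) / 2.
parkerWeights <- function(gammas, betas, Gamma) {
  g <- pmin(pmax(gammas, -Gamma + 1e-12), Gamma - 1e-12)
  W <- matrix(1, length(gammas), length(betas))
  for (j in seq_along(betas)) {
    b <- betas[j]
    w <- rep(1, length(g))
    a1 <- 2 * (Gamma - g)       # ramp-up ends
    a2 <- pi - 2 * g            # ramp-down starts
    up <- b < a1
    w[up] <- sin(pi / 4 * b / (Gamma - g[up]))^2
    down <- b > a2
    w[down] <- sin(pi / 4 * (pi + 2 * Gamma - b) / (Gamma + g[down]))^2
    w[b > pi + 2 * Gamma] <- 0
    W[, j] <- w
  }
  W
}

#' Filtered backprojection / FDK reconstruction
#'
#' Analytic reference reconstruction: ramp-filtered backprojection with a
#' Hamming-apodized filter (alpha from the configuration, default 0.54).
#' Parallel-beam data use plain FBP; fan-beam short scans (span >= 180 degrees
#' plus the fan angle) get Parker weighting; full 360 fan scans get uniform
#' 1/2 redundancy weighting; cone-beam data use the standard FDK cosine
#' weighting with single-circle backprojection.
#'
#' @param projections a [ProjectionSet-class] with uniform angles.
#' @param config a [ReconConfig-class]; only `hammingAlpha` is used.
#' @return A [VoxelVolume-class] of attenuation (1/mm).
#' @export
reconstructFDK <- function(projections, config = ReconConfig("fdk")) {
  g <- geometry(projections)
  alpha <- config@hammingAlpha
  span <- angularSpan(g)
  step <- if (length(g@angles) > 1) mean(diff(g@angles)) else 0
  angRad <- g@angles * pi / 180
  stepRad <- step * pi / 180
  vsmm <- g@voxelSize / 1000
  pitchIso <- detPitchIso(g)
  s <- g@volShape

  if (g@modality == "parallel2d") {
    if (span + step + 1e-9 < 180)
      stop(sprintf(
        "angular span %.3g deg insufficient for parallel FBP (needs >= %.3g)",
        span, 180 - step))
    q <- rampFilter(projData(projections), pitchIso, alpha)
    scale <- stepRad * if (span + step > 300) 0.5 else 1
    v <- cpp_bp_par2d(q * scale, s[1], s[2], angRad, pitchIso / vsmm)
    return(VoxelVolume(array(v, dim = s), g@voxelSize))
  }

  fan <- fanAngleDeg(g)
  fullScan <- span + step + 1e-9 >= 360
  if (!fullScan && span + step + 1e-9 < 180 + fan)
    stop(sprintf(
      "angular span %.4g deg insufficient for a short scan (needs >= %.4g; deficit %.4g deg)",
      span, 180 + fan - step, 180 + fan - step - span))

  ndu <- g@detCount[1]
  u <- (seq_len(ndu) - (ndu + 1) / 2) * pitchIso   # mm at isocenter

  if (g@modality == "fan2d") {
    p <- projData(projections)
    cw <- g@sad / sqrt(g@sad^2 + u^2)
    p <- p * cw
    if (fullScan) {
      p <- p * 0.5
    } else {
      Gamma <- (span * pi / 180 - pi) / 2
      gammas <- atan2(u, g@sad)
      betas <- (g@angles - g@angles[1]) * pi / 180
      p <- p * parkerWeights(gammas, betas, Gamma)
    }
    q <- rampFilter(p, pitchIso, alpha)
    v <- cpp_bp_fan2d(q * stepRad, s[1], s[2], angRad, pitchIso / vsmm,
                      g@sad * 1000 / g@voxelSize)
    return(VoxelVolume(array(v, dim = s), g@voxelSize))
  }

  # cone3d: FDK
  ndv <- g@detCount[2]
  vco <- (seq_len(ndv) - (ndv + 1) / 2) * pitchIso
  p <- projData(projections)
  cw <- outer(u, vco, function(uu, vv) g@sad / sqrt(g@sad^2 + uu^2 + vv^2))
  if (!fullScan) {
    Gamma <- (span * pi / 180 - pi) / 2
    gammas <- atan2(u, g@sad)
    betas <- (g@angles - g@angles[1]) * pi / 180
    pw <- parkerWeights(gammas, betas, Gamma)
  }
  q <- array(0, dim = dim(p))
  for (j in seq_len(ndv)) {
    pj <- p[, j, ] * cw[, j]
    pj <- if (fullScan) pj * 0.5 else pj * pw
    q[, j, ] <- rampFilter(pj, pitchIso, alpha)
  }
  v <- cpp_bp_cone3d(as.double(q * stepRad), ndu, ndv, s[1], s[2], s[3],
                     angRad, pitchIso / vsmm, g@sad * 1000 / g@voxelSize)
  VoxelVolume(array(v, dim = s), g@voxelSize)
}
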