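#' Mean absolute error between two images or volumes
#'
#' \deqn{\mathrm{MAE} = \frac{1}{m}\sum_{i=1}^m |y(i) - y'(i)|}
#' over all \eqn{m} pixels.  Inputs are compared as given; normalise
#' beforehand (e.g. to unit mean over a signal region) when comparing
#' reconstructions on different intensity scales.
#'
#' @param y,yPrime arrays of identical shape.
#' @return the scalar MAE.
#' @export
mae <- function(y, yPrime) {
  if (!identical(dim(y), dim(yPrime)) || length(y) != length(yPrime))
    stop("shape mismatch between y and yPrime")
  mean(abs(y - yPrime))
}

#' Signal-to-noise ratio in dB from signal/noise regions
#'
#' \deqn{\mathrm{SNR(dB)} = 10 \log_{10}
#'   \frac{\mathrm{mean(signal)} - \mathrm{mean(noise)}}{\mathrm{sd(noise)}}}
#' using a region containing structure and a region without.
#'
#' @param image numeric array.
#' @param signalMask,noiseMask logical arrays selecting the two disjoint,
#'   non-empty regions.
#' @return SNR in dB.
#' @export
snrDb <- function(image, signalMask, noiseMask) {
  if (!any(signalMask) || !any(noiseMask))
    stop("signal and noise masks must both be non-empty")
  if (any(signalMask & noiseMask))
    stop("signal and noise masks must be disjoint")
  s <- image[signalMask]
  n <- image[noiseMask]
  sdN <- stats::sd(n)
  if (sdN == 0) stop("noise region has zero standard deviation")
  ratio <- (mean(s) - mean(n)) / sdN
  if (ratio <= 0)
    stop("undefined SNR: mean(signal) <= mean(noise)")
  10 * log10(ratio)
}

#' Translation registration between two images
#'
#' Integer cross-correlation shift followed by zoomed-DFT subpixel
#' refinement.  Applying the returned shift to \code{mov} maximises its
#' correlation with \code{ref}.  A peak-contrast ratio below 2 (peak over
#' annulus median) flags a low-confidence result, e.g. for structureless
#' inputs.
#'
#' @param ref,mov real matrices of identical shape.
#' @param upsample subpixel refinement factor.
#' @return list with \code{shift} (named c(y, x): \code{mov} is \code{ref}
#'   displaced by this many pixels), \code{confidence} (contrast ratio)
#'   and \code{lowConfidence}.
#' @export
registerTranslation <- function(ref, mov, upsample = 20L) {
  if (!identical(dim(ref), dim(mov))) stop("shape mismatch")
  if (length(ref) == 0L) stop("empty images")
  Fr <- fftShift(stats::fft(ifftShift(ref)))
  Fm <- fftShift(stats::fft(ifftShift(mov)))
  Q <- Fm * Conj(Fr)
  corr <- fftShift(stats::fft(ifftShift(Q), inverse = TRUE)) / length(Q)
  M <- Mod(corr)
  d <- dim(M)
  imax <- arrayInd(which.max(M), d)
  ry <- outer(seq_len(d[1L]) - imax[1L], rep(1, d[2L]))
  rx <- outer(rep(1, d[1L]), seq_len(d[2L]) - imax[2L])
  rr <- sqrt(ry^2 + rx^2)
  # near-extreme normalisation against everything far from the peak: the
  # argmax of a structureless surface is itself an extreme value, so it
  # scores ~1 here, while a genuine peak towers over the background even
  # after its autocorrelation shoulder is excluded
  far <- rr > 15
  if (!any(far)) far <- rr > max(rr) / 2
  lev <- stats::quantile(M[far], 0.995, names = FALSE)
  confidence <- if (lev > 0) M[imax[1L], imax[2L]] / lev else Inf
  # subpixel: corr(s) = (1/N) sum_k Q(k) exp(+2i pi k.s); evaluate a zoomed
  # grid around the integer peak via the conjugate zoom transform
  sy0 <- centeredCoords(d[1L])[imax[1L]]
  sx0 <- centeredCoords(d[2L])[imax[2L]]
  sy <- sy0 + seq(-1, 1, by = 1 / upsample)
  sx <- sx0 + seq(-1, 1, by = 1 / upsample)
  Z <- Conj(zoomDFT2(Conj(Q), sy / d[1L], sx / d[2L])) / length(Q)
  zi <- arrayInd(which.max(Mod(Z)), dim(Z))
  list(shift = c(y = sy[zi[1L]], x = sx[zi[2L]]),
       confidence = confidence,
       lowConfidence = confidence < 2)
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated width at half of (max - baseline), where the
#' baseline is the profile minimum.
#'
#' @param profile single-peaked intensity samples.
#' @param spacing sample spacing (nm per sample).
#' @return width in the units of \code{spacing}.
#' @export
fwhm <- function(profile, spacing = 1) {
  n <- length(profile)
  if (n < 3L) stop("no half-maximum crossing found: profile too short")
  ipk <- which.max(profile)
  base <- min(profile)
  half <- base + (profile[ipk] - base) / 2
  left <- NA_real_
  for (i in seq(ipk, 2L)) {
    if (profile[i - 1L] <= half && profile[i] >= half) {
      left <- (i - 1L) + (half - profile[i - 1L]) / (profile[i] - profile[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk, n - 1L)) {
    if (profile[i + 1L] <= half && profile[i] >= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1L])
      break
    }
  }
  if (is.na(left) || is.na(right))
    stop("no half-maximum crossing found on both sides of the peak")
  (right - left) * spacing
}
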