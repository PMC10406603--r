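# Dipole-orientation mapping from the angle-resolved data.
#
# In grating-based SIM the excitation is linearly polarized with an
# azimuth that rotates with the pattern angle, so the three per-angle
# widefield images form a three-point polarization modulation series at
# every pixel; a cos(2x) fit recovers the in-plane dipole azimuth.

# smallest distance between two dipole axes (angles modulo pi)
.angdiffpi <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

# Gaussian smoothing by FFT (periodic boundaries; fields are slowly
# varying so the wrap-around is immaterial)
.gaussSmooth2 <- function(img, sigma) {
  d <- dim(img)
  fy <- centeredFreqs(d[1L]); fx <- centeredFreqs(d[2L])
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, `+`))
  Re(fftShift(stats::fft(ifftShift(fftShift(stats::fft(ifftShift(img))) * H),
                         inverse = TRUE))) / length(img)
}

#' Illumination-nonuniformity calibration from bead fields
#'
#' Builds a smooth intensity map per angle from a dense bead field by
#' normalised convolution (Gaussian-smoothed masked intensity divided by
#' the smoothed mask -- interpolation across the gaps between beads), and
#' returns the ratio images
#' \code{calib1 = calib_ang2 / calib_ang1},
#' \code{calib2 = calib_ang3 / calib_ang1}.
#'
#' @param beadsAng1,beadsAng2,beadsAng3 widefield bead images of the same
#'   field, one per pattern angle (each the average of its five phases).
#' @param smoothSigma Gaussian interpolation scale, px.
#' @param maskQuantile intensities above this quantile of angle 1 count
#'   as bead coverage.
#' @return a \linkS4class{CalibrationRatios}; pixels whose smoothed
#'   coverage is too thin are masked out.
#' @export
calibrationRatios <- function(beadsAng1, beadsAng2, beadsAng3,
                              smoothSigma = 8, maskQuantile = 0.6) {
  thr <- stats::quantile(beadsAng1, maskQuantile)
  cover <- beadsAng1 >= thr
  if (!any(cover)) stop("empty bead mask: no pixels above the coverage threshold")
  sm <- .gaussSmooth2(cover * 1, smoothSigma)
  smooth1 <- .gaussSmooth2(beadsAng1 * cover, smoothSigma) / pmax(sm, 1e-12)
  smooth2 <- .gaussSmooth2(beadsAng2 * cover, smoothSigma) / pmax(sm, 1e-12)
  smooth3 <- .gaussSmooth2(beadsAng3 * cover, smoothSigma) / pmax(sm, 1e-12)
  ok <- sm > 0.05 & smooth1 > 0
  c1 <- smooth2 / smooth1
  c2 <- smooth3 / smooth1
  c1[!ok] <- NA_real_
  c2[!ok] <- NA_real_
  new("CalibrationRatios", calib1 = c1, calib2 = c2, mask = ok)
}

#' Estimate the per-pixel dipole orientation
#'
#' Per-pixel least-squares fit of the three-angle polarization series
#' \eqn{I_a = dc + A\cos 2(\alpha_a - \theta)} through the linear basis
#' \{1, cos 2a, sin 2a\}; with exactly three distinct azimuths the fit is
#' exactly determined.  When calibration ratios are supplied the inputs
#' are first corrected to \eqn{I_1, I_2/\mathrm{calib}_1,
#' I_3/\mathrm{calib}_2}.  The orientation is
#' \eqn{\theta = \frac12\,\mathrm{atan2}(s, c)} mapped into
#' \eqn{[0, \pi)} (a dipole is a line, not an arrow).  Pixels whose
#' relative modulation falls below \code{minModulation}, or whose mean
#' intensity is within 3 background standard deviations of zero, carry no
#' reliable angle and are masked.
#'
#' @param angleMeans list of three widefield images (per-angle phase
#'   averages of the focal slice).
#' @param patternAngles the three excitation polarization azimuths, rad,
#'   distinct modulo pi.
#' @param calib optional \linkS4class{CalibrationRatios}.
#' @param minModulation significance floor on amplitude/dc.
#' @param backgroundSd background noise sd for the intensity floor
#'   (0 disables that criterion).
#' @return an \linkS4class{OrientationMap}.
#' @export
estimateDipoleOrientation <- function(angleMeans, patternAngles,
                                      calib = NULL, minModulation = 0.05,
                                      backgroundSd = 0) {
  if (length(angleMeans) < 3L || length(patternAngles) < 3L)
    stop("need three angle images and three polarization azimuths")
  da <- outer(patternAngles, patternAngles, `-`)
  if (any(abs(sin(da[upper.tri(da)])) < 1e-9))
    stop("polarization azimuths duplicated modulo pi")
  I1 <- angleMeans[[1L]]; I2 <- angleMeans[[2L]]; I3 <- angleMeans[[3L]]
  if (!is.null(calib)) {
    I2 <- I2 / calib@calib1
    I3 <- I3 / calib@calib2
  }
  A <- cbind(1, cos(2 * patternAngles), sin(2 * patternAngles))
  X <- solve(A)
  dc <- X[1, 1] * I1 + X[1, 2] * I2 + X[1, 3] * I3
  cc <- X[2, 1] * I1 + X[2, 2] * I2 + X[2, 3] * I3
  ss <- X[3, 1] * I1 + X[3, 2] * I2 + X[3, 3] * I3
  amplitude <- sqrt(cc^2 + ss^2)
  theta <- (0.5 * atan2(ss, cc)) %% pi
  mask <- is.finite(dc) & dc > 0 & amplitude / pmax(dc, 1e-12) >= minModulation
  if (backgroundSd > 0) mask <- mask & dc > 3 * backgroundSd
  if (!is.null(calib)) mask <- mask & calib@mask
  theta[!mask] <- NA_real_
  new("OrientationMap", theta = theta, amplitude = amplitude,
      dc = dc, mask = mask)
}

#' Per-angle widefield images of a raw stack
#'
#' Averages the phase steps of each angle (cancelling the pattern orders)
#' and extracts one focal slice, yielding the three inputs of
#' \code{\link{estimateDipoleOrientation}}.
#'
#' @param stack a \linkS4class{RawStack}.
#' @param z focal slice index; default the central plane.
#' @return list of matrices, one per angle.
#' @export
angleMeans <- function(stack, z = NULL) {
  d <- dim(stack@data)
  if (is.null(z)) z <- floor(d[3L] / 2) + 1L
  lapply(seq_len(d[1L]), function(a) {
    am <- apply(array(stack@data[a, , z, , ], d[c(2L, 4L, 5L)]), c(2L, 3L), mean)
    am
  })
}

#' HSV composite of an orientation map
#'
#' Hue encodes the dipole azimuth, value the mean intensity; masked
#' pixels are black.  Returns an rgb array suitable for
#' \code{png::writePNG}; display is best-effort, not bit-specified.
#'
#' @param omap an \linkS4class{OrientationMap}.
#' @return numeric array \code{[y, x, 3]} in [0, 1].
#' @export
orientationComposite <- function(omap) {
  v <- omap@dc / max(omap@dc, na.rm = TRUE)
  v[!omap@mask] <- 0
  h <- omap@theta / pi
  h[!omap@mask] <- 0
  cols <- grDevices::hsv(pmin(pmax(h, 0), 1), 1, pmin(pmax(v, 0), 1))
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(nrow(omap@theta), ncol(omap@theta), 3L))
  out[, , 1L] <- matrix(rgb[1L, ], nrow(omap@theta))
  out[, , 2L] <- matrix(rgb[2L, ], nrow(omap@theta))
  out[, , 3L] <- matrix(rgb[3L, ], nrow(omap@theta))
  out
}
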