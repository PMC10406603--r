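#' Construct a two-step filter specification
#'
#' @param notchDepthDC,notchDepthP attenuation depths in \code{[0,1)} of the
#'   Gaussian notches at DC and at the pattern peaks.
#' @param notchSigma notch width in cycles/pixel; \code{NA} (default)
#'   scales with the input image: 2 frequency samples, i.e. \code{2/N}.
#' @param wienerW Wiener regularisation (primary user knob).
#' @param apoGamma apodization sharpness exponent.
#' @param apoCutoffLateral,apoCutoffAxial extended-support cutoffs,
#'   cycles/pixel; \code{NA} derives them from the estimated pattern.
#' @param notchEnabled set FALSE to skip Filter 1 (diagnostics).
#' @return a \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(notchDepthDC = 0.98, notchDepthP = 0.9,
                       notchSigma = NA_real_, wienerW = 0.05,
                       apoGamma = 0.9, apoCutoffLateral = NA_real_,
                       apoCutoffAxial = NA_real_, notchEnabled = TRUE) {
  new("FilterSpec",
      notchDepthDC = notchDepthDC, notchDepthP = notchDepthP,
      notchSigma = notchSigma, wienerW = wienerW, apoGamma = apoGamma,
      apoCutoffLateral = apoCutoffLateral, apoCutoffAxial = apoCutoffAxial,
      notchEnabled = notchEnabled)
}

#' Lateral notch filter
#'
#' Product of inverted Gaussians, one per center:
#' \deqn{w(k) = \prod_c \left[1 - d_c \exp(-|k - c|^2 / (2\sigma^2))\right]}
#' evaluated on the lateral frequency plane (the residual illumination
#' peaks it targets sit at fixed lateral positions for every kz).  Weights
#' lie in \code{(0, 1]} and approach 1 far from every center.
#'
#' @param freqY,freqX DC-centered frequency axes, cycles/pixel.
#' @param centers matrix with columns \code{(ky, kx)}, one row per center
#'   (typically DC, +/-p and +/-2p of one angle).
#' @param depths attenuation per center, each in \code{[0, 1)}.
#' @param sigma Gaussian width, cycles/pixel.
#' @return real matrix \code{length(freqY) x length(freqX)}.
#' @export
notchFilter <- function(freqY, freqX, centers, depths, sigma) {
  centers <- matrix(centers, ncol = 2L)
  if (any(depths >= 1) || any(depths < 0))
    stop("notch depths must lie in [0, 1)")
  if (sigma <= 0) stop("notch sigma must be positive")
  w <- matrix(1, length(freqY), length(freqX))
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((freqY - centers[i, 1L])^2, (freqX - centers[i, 2L])^2, `+`)
    w <- w * (1 - depths[i] * exp(-d2 / (2 * sigma^2)))
  }
  w
}

#' Apply a notch weight to a band transfer function
#'
#' Elementwise product of a band OTF with a lateral notch weight
#' (broadcast over kz).  The attenuated OTF replaces the plain band OTF
#' inside the Wiener numerator: where the notch dips, the band's
#' contribution is withdrawn, suppressing the residual pattern peaks and
#' the DC pedestal without touching the rest of the passband.
#'
#' @param bandOtfArr complex 3-D band OTF \code{[kz, ky, kx]}.
#' @param notch real notch matrix \code{[ky, kx]} (or a full 3-D array on
#'   the same grid).
#' @return the attenuated complex array.
#' @export
attenuatedBandOTF <- function(bandOtfArr, notch) {
  d <- dim(bandOtfArr)
  if (is.matrix(notch)) {
    if (!identical(dim(notch), d[2:3]))
      stop("notch grid does not match the band OTF lateral grid")
    bandOtfArr * array(rep(notch, each = d[1L]), d)
  } else {
    if (!identical(dim(notch), d))
      stop("notch grid does not match the band OTF grid")
    bandOtfArr * notch
  }
}

#' Apodization filter on the extended support
#'
#' Generalized-ellipsoid power roll-off
#' \deqn{w(k) = (1 - d(k))^\gamma, \quad
#'   d(k) = \sqrt{(|k_{lat}|/c_{lat})^2 + (k_z/c_{ax})^2} \le 1}
#' and 0 outside, monotone non-increasing along every ray from DC with
#' \code{w(DC) = 1}.  Applied once to the assembled spectrum, it shapes
#' the effective PSF and prevents ringing at the hard support edge.
#'
#' @param dims \code{c(nz, ny, nx)} of the padded grid.
#' @param latScale cycles/pixel spanned by one lateral frequency sample
#'   times the grid size (i.e. lateral frequencies are
#'   \code{centeredFreqs(n) * latScale}); use 2 for the 2x padded grid so
#'   frequencies stay in cycles per original pixel.
#' @param cutoffLateral,cutoffAxial support cutoffs, cycles/pixel (z in
#'   cycles per z-step).
#' @param gamma sharpness exponent.
#' @return real 3-D weight array in \code{[0, 1]}.
#' @export
apodizationFilter <- function(dims, latScale, cutoffLateral, cutoffAxial,
                              gamma = 0.9) {
  if (cutoffLateral <= 0 || cutoffAxial <= 0)
    stop("apodization cutoffs must be positive")
  fz <- centeredFreqs(dims[1L])
  fy <- centeredFreqs(dims[2L]) * latScale
  fx <- centeredFreqs(dims[3L]) * latScale
  g <- grid3(fz, fy, fx)
  d <- sqrt((sqrt(g$y^2 + g$x^2) / cutoffLateral)^2 + (g$z / cutoffAxial)^2)
  w <- pmax(1 - d, 0)^gamma
  w[d > 1] <- 0
  w
}
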