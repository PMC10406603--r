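#' Shift a band spectrum to its true frequency position
#'
#' Embeds the band into the laterally padded reconstruction grid, then
#' translates its content by the requested frequency offset: the padded
#' spectrum is inverse-transformed, multiplied by the complex exponential
#' \eqn{\exp(2i\pi\, s \cdot r)} on centered coordinates, and transformed
#' back -- an exact subpixel translation (periodic sinc interpolation in
#' frequency space).  The order-m band is moved by \eqn{-m p} laterally so
#' the object information it carries lands at its true frequencies; the
#' axial side-lobe structure of the first-order bands is handled by their
#' two-lobe band OTF, not by shifting the data axially.
#'
#' @param band complex DC-centered spectrum, either on the original grid
#'   or (with \code{embedded = TRUE}) already on the padded grid.
#' @param lateralShift \code{c(kx, ky)} in cycles per original pixel; the
#'   spectrum content is translated by this vector.
#' @param axialShift cycles per z-step.
#' @param padFactor lateral padding factor.
#' @param embedded set TRUE when \code{band} is already padded (e.g. a
#'   band OTF from \code{\link{bandOTF}}).
#' @return complex spectrum on the padded grid.
#' @export
shiftBand <- function(band, lateralShift = c(0, 0), axialShift = 0,
                      padFactor = 2L, embedded = FALSE) {
  d <- dim(band)
  E <- if (embedded) band else
    embedLateral(zeroNyquist(band), padFactor * d[2L], padFactor * d[3L])
  # per-sample cycles on the padded grid
  s <- c(axialShift, lateralShift[2L] / padFactor, lateralShift[1L] / padFactor)
  if (any(abs(s) > 0.5))
    stop("shift beyond the padded-grid Nyquist")
  shiftSpectrum(E, -s)
}

.notchForAngle <- function(freqY, freqX, p, spec, sigma) {
  centers <- rbind(c(0, 0),
                   c(p[2L], p[1L]), -c(p[2L], p[1L]),
                   2 * c(p[2L], p[1L]), -2 * c(p[2L], p[1L]))
  depths <- c(spec@notchDepthDC, rep(spec@notchDepthP, 4L))
  notchFilter(freqY, freqX, centers, depths, sigma)
}

#' Generalized Wiener combination of all separated bands
#'
#' Assembles the super-resolved spectrum on the 2x laterally padded grid:
#' \deqn{S(k) = \frac{\sum_{a,m} d_m\, \overline{O^{notch}_{a,m}(k)}\,
#'   \tilde B_{a,m}(k)}{\sum_{a,m} d_m^2\, |O_{a,m}(k)|^2 + w^2}\; A(k)}
#' where \eqn{\tilde B} are the phase-corrected, shifted bands, \eqn{d_m}
#' the band weights derived from the modulation depths (1, m1/2, m2/2
#' for orders 0, 1, 2), \eqn{O_{a,m}} the shifted OTFs, \eqn{w} the Wiener
#' regularisation and \eqn{A} the apodization.  The first-order bands
#' (weight m1/2) carry the two-lobe transfer function
#' \eqn{[O(k - q_z) + O(k + q_z)]/2} of scanned three-beam acquisition
#' (see \code{\link{bandOTF}}); its support on the axial frequency axis
#' is what fills the widefield missing cone after the lateral shift.
#' Filter 1 enters as
#' the notch attenuation of the numerator OTFs only: withdrawing a band's
#' vote near DC and the pattern peaks suppresses those peaks, whereas
#' notching the denominator as well would cancel the attenuation again
#' (the quotient would renormalise) and instead amplify them.
#'
#' @param bandsets list of \linkS4class{BandSet}, one per angle.
#' @param params list of \linkS4class{PatternParams}, one per angle.
#' @param otf the widefield \linkS4class{OTF3D} on the original grid.
#' @param filters a \linkS4class{FilterSpec}.
#' @param padFactor lateral padding factor (2 doubles the represented
#'   lateral frequency range).
#' @param orders which band orders to include (default all; restricting to
#'   0 yields the Wiener-deconvolved widefield path).
#' @return an \linkS4class{AssembledSpectrum}.
#' @export
wienerCombine <- function(bandsets, params, otf, filters = filterSpec(),
                          padFactor = 2L, orders = -2:2) {
  if (length(bandsets) == 0L) stop("empty band list")
  if (length(bandsets) != length(params))
    stop("need one PatternParams per angle")
  d <- dim(bandsets[[1L]]@bands[["0"]])
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  pd <- c(nz, padFactor * ny, padFactor * nx)
  g <- bandsets[[1L]]@geometry
  freqY <- centeredFreqs(pd[2L]) * padFactor  # cycles per original pixel
  freqX <- centeredFreqs(pd[3L]) * padFactor
  sigma <- if (is.na(filters@notchSigma)) 2 / max(ny, nx) else filters@notchSigma

  O0 <- bandOTF(otf, 0L, 0, padFactor)
  num <- array(0 + 0i, pd)
  den <- array(0, pd)
  support <- array(FALSE, pd)
  weightLog <- list()

  for (a in seq_along(bandsets)) {
    bs <- bandsets[[a]]
    pp <- params[[a]]
    if (any(vapply(bs@bands, function(b) any(is.na(b)), logical(1L))))
      stop(sprintf("NaN in separated bands of angle %d", a))
    O1 <- if (any(abs(orders) == 1L)) bandOTF(otf, 1L, pp@qz, padFactor) else NULL
    notch <- if (filters@notchEnabled)
      .notchForAngle(freqY, freqX, pp@p, filters, sigma)
    else matrix(1, pd[2L], pd[3L])
    notch3 <- array(rep(notch, each = nz), pd)
    for (m in orders) {
      dm <- switch(as.character(abs(m)), "0" = 1, "1" = pp@m1 / 2, "2" = pp@m2 / 2)
      B <- bs@bands[[as.character(m)]] * exp(-1i * m * pp@phi0)
      Bs <- shiftBand(B, -m * pp@p, 0, padFactor)
      Om <- if (abs(m) == 1L) O1 else O0
      Os <- shiftBand(Om, -m * pp@p, 0, padFactor, embedded = TRUE)
      num <- num + dm * Conj(Os * notch3) * Bs
      den <- den + dm^2 * Mod(Os)^2
      support <- support | (Mod(Os) > 1e-3)
      weightLog[[sprintf("a%d_m%+d", a, m)]] <- dm
    }
  }
  S <- num / (den + filters@wienerW^2)

  pmax2 <- max(vapply(params, function(x) sqrt(sum(x@p^2)), numeric(1L)))
  qzmax <- max(vapply(params, function(x) x@qz, numeric(1L)))
  cutLat <- filters@apoCutoffLateral
  if (is.na(cutLat))
    cutLat <- min(lateralCutoff(g, "px") + 2 * pmax2, padFactor * 0.5)
  cutAx <- filters@apoCutoffAxial
  if (is.na(cutAx))
    cutAx <- min(axialCutoff(g, "px") + qzmax, 0.5)
  apo <- apodizationFilter(pd, padFactor, cutLat, cutAx, filters@apoGamma)
  S <- S * apo

  new("AssembledSpectrum", values = S, effectiveSupport = support,
      provenance = list(weights = weightLog, wienerW = filters@wienerW,
                        notchSigma = sigma, apoCutoffLateral = cutLat,
                        apoCutoffAxial = cutAx))
}

#' Reconstruct a super-resolved volume from a raw 3D-SIM stack
#'
#' End-to-end deterministic pipeline: validation, per-angle intensity
#' normalisation, lateral taper, per-angle 3-D transform and band
#' separation, pattern-parameter estimation with the second-to-first
#' order fallback, band shifting, generalized Wiener combination with the
#' two-step notch/apodization filter, inverse transform, and optional
#' clipping of negative intensities.
#'
#' @param stack a \linkS4class{RawStack}.
#' @param taperAlpha lateral Tukey taper fraction.
#' @param filters a \linkS4class{FilterSpec}.
#' @param rMin,rMinFallback,searchAnnulus,upsample,mMin estimation
#'   settings, see \code{\link{estimatePattern}}.
#' @param freqOverride optional list (one \code{c(kx, ky)} per angle) of
#'   known pattern frequencies, cycles/px.
#' @param forceFallback force first-order estimation for every angle.
#' @param clipNegative clip negative output intensities at 0 (recorded in
#'   the provenance).
#' @param padFactor lateral padding/upsampling factor.
#' @return a \linkS4class{Reconstruction}; its provenance records the
#'   estimated parameters of every angle, filter settings, validation
#'   warnings and the clipped-voxel fraction.
#' @examples
#' \donttest{
#' gt <- makePhantom("beads", c(8, 64, 64), seed = 1)
#' sim <- simulateRawStack(gt, simConfig(peakPhotons = 500, seed = 1))
#' rec <- reconstructSIM(sim$stack)
#' rec
#' }
#' @export
reconstructSIM <- function(stack, taperAlpha = 0.1, filters = filterSpec(),
                           rMin = 4, rMinFallback = 2,
                           searchAnnulus = c(0.3, 1.1), upsample = 32L,
                           mMin = 0.15, freqOverride = NULL,
                           forceFallback = FALSE, clipNegative = TRUE,
                           padFactor = 2L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("reconstruction stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  g <- stack@geometry
  rep_ <- stage("validate", {
    v <- validateStack(stack)
    if (length(v$errors))
      stop(paste(v$errors, collapse = "; "))
    v
  })
  dat <- stack@data
  d <- dim(dat)
  nA <- d[1L]; nP <- d[2L]
  # per-angle global normalisation: bleaching/illumination drift between
  # angles otherwise leaks into the separated bands
  m1 <- mean(dat[1L, , , , ])
  for (a in seq_len(nA)[-1L]) {
    ma <- mean(dat[a, , , , ])
    if (ma > 0) dat[a, , , , ] <- dat[a, , , , ] * (m1 / ma)
  }
  phases <- 2 * pi * (seq_len(nP) - 1L) / nP
  otf <- stage("otf", psfToOTF(computePSF(g, d[3:5]), g))
  bandsets <- vector("list", nA)
  params <- vector("list", nA)
  for (a in seq_len(nA)) {
    bandsets[[a]] <- stage("separation",
      separateBands(array(dat[a, , , , ], d[2:5]), phases, taperAlpha, g, a))
    fo <- if (!is.null(freqOverride)) freqOverride[[a]] else NULL
    params[[a]] <- stage("estimation",
      estimatePattern(bandsets[[a]], otf, rMin, rMinFallback, searchAnnulus,
                      upsample, mMin, fo, forceFallback))
  }
  asm <- stage("assembly",
    wienerCombine(bandsets, params, otf, filters, padFactor))
  volC <- stage("inverse transform", iftn(asm@values))
  imagRel <- max(abs(Im(volC))) / max(abs(Re(volC)))
  vol <- Re(volC)
  clipFraction <- 0
  if (clipNegative) {
    clipFraction <- mean(vol < 0)
    vol[vol < 0] <- 0
  }
  new("Reconstruction", volume = vol, geometry = g,
      provenance = list(
        params = lapply(params, function(p) list(
          p = p@p, qz = p@qz, phi0 = p@phi0, m1 = p@m1, m2 = p@m2,
          source = p@source, reliability = p@reliability)),
        filters = asm@provenance,
        taperAlpha = taperAlpha,
        warnings = rep_$warnings,
        clipNegative = clipNegative,
        clipFraction = clipFraction,
        imagRel = imagRel,
        inputDim = d[3:5],
        version = as.character(utils::packageVersion("sim3dr"))))
}

#' Widefield volume of a raw stack
#'
#' Average over all angles and phases: the root-of-unity cancellation of
#' the pattern orders leaves only the conventional diffraction-limited
#' image.
#'
#' @param stack a \linkS4class{RawStack}.
#' @return real 3-D array \code{[z, y, x]} on the original grid.
#' @export
widefieldVolume <- function(stack) {
  d <- dim(stack@data)
  array(apply(stack@data, 3:5, mean), d[3:5])
}
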