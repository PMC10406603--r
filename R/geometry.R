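#' Construct an acquisition geometry
#'
#' Defaults describe an OMX-type oil-immersion 3D-SIM acquisition:
#' 3 pattern angles, 5 phase steps, 488/525 nm excitation/emission, NA 1.4
#' in n = 1.518 oil, 80 nm lateral pixels and 125 nm z-steps.
#'
#' @param nAngles,nPhases pattern angles and phase steps per angle.
#' @param lambdaExc,lambdaEm excitation/emission wavelengths, nm.
#' @param na objective numerical aperture.
#' @param nImmersion immersion refractive index.
#' @param dxy,dz lateral pixel size and axial step, nm.
#' @param layout raw TIFF page ordering: \code{"OMX"}, \code{"NSIM"} or
#'   \code{"HOMEBUILT"}.
#' @return an \linkS4class{AcquisitionGeometry}.
#' @examples
#' g <- acquisitionGeometry()
#' lateralCutoff(g, "px")
#' @export
acquisitionGeometry <- function(nAngles = 3L, nPhases = 5L,
                                lambdaExc = 488, lambdaEm = 525,
                                na = 1.4, nImmersion = 1.518,
                                dxy = 80, dz = 125, layout = "OMX") {
  new("AcquisitionGeometry",
      nAngles = as.integer(nAngles), nPhases = as.integer(nPhases),
      lambdaExc = lambdaExc, lambdaEm = lambdaEm,
      na = na, nImmersion = nImmersion,
      dxy = dxy, dz = dz, layout = layout)
}

#' Detection support cutoffs
#'
#' \code{lateralCutoff} returns the widefield lateral OTF cutoff
#' \eqn{2\,\mathrm{NA}/\lambda_{em}}, \code{axialCutoff} the axial cutoff
#' \eqn{(n - \sqrt{n^2 - \mathrm{NA}^2})/\lambda_{em}}.
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param units \code{"nm"} for cycles/nm or \code{"px"} for cycles per
#'   pixel (lateral) / per z-step (axial).
#' @return the cutoff frequency.
#' @export
lateralCutoff <- function(geometry, units = c("nm", "px")) {
  units <- match.arg(units)
  kc <- 2 * geometry@na / geometry@lambdaEm
  if (units == "px") kc * geometry@dxy else kc
}

#' @rdname lateralCutoff
#' @export
axialCutoff <- function(geometry, units = c("nm", "px")) {
  units <- match.arg(units)
  n <- geometry@nImmersion
  kz <- (n - sqrt(n^2 - geometry@na^2)) / geometry@lambdaEm
  if (units == "px") kz * geometry@dz else kz
}

#' Axial pattern frequency of a three-beam interference pattern
#'
#' Three-beam interference ties the axial modulation frequency to the
#' lateral first-order frequency: the side beams propagate with axial
#' wavenumber \eqn{\sqrt{(n/\lambda_{exc})^2 - |p|^2}}, so the beat against
#' the axial center beam is
#' \deqn{q_z = (n - \sqrt{n^2 - |p|^2 \lambda_{exc}^2}) / \lambda_{exc}.}
#' Because the geometry fixes it, \eqn{q_z} is computed, never estimated
#' from noisy data.
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param pLateral magnitude of the lateral first-order pattern frequency,
#'   cycles per pixel.
#' @param units \code{"px"} for cycles per z-step, \code{"nm"} for cycles/nm.
#' @return the axial pattern frequency.
#' @export
axialPatternFreq <- function(geometry, pLateral, units = c("px", "nm")) {
  units <- match.arg(units)
  pm <- pLateral / geometry@dxy                  # cycles/nm
  n <- geometry@nImmersion
  arg <- n^2 - (pm * geometry@lambdaExc)^2
  if (arg <= 0)
    stop("lateral pattern frequency too high for a propagating side beam (",
         sprintf("|p| = %.4g cycles/nm, limit %.4g", pm, n / geometry@lambdaExc), ")")
  qz <- (n - sqrt(arg)) / geometry@lambdaExc     # cycles/nm
  if (units == "px") qz * geometry@dz else qz
}
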