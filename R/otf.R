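#' Scalar pupil-propagation point spread function
#'
#' Computes a 3-D widefield PSF by defocus propagation of a uniform
#' circular pupil: for each z-plane the coherent field is the inverse 2-D
#' transform of \eqn{P(k)\,\exp(i 2\pi z \sqrt{(n/\lambda_{em})^2 -
#' |k|^2})} over the pupil disc \eqn{|k| \le NA/\lambda_{em}}, and the PSF
#' is its squared magnitude, normalised to unit total sum.  This scalar
#' model (no vectorial or apodization factors) is the standard baseline
#' and is shared by the simulator and the reconstruction filters, so the
#' two sides are self-consistent.
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param shape integer \code{c(nz, ny, nx)} grid size.
#' @param dxy,dz sampling overrides in nm (default: the geometry values);
#'   used internally to build OTFs on the 2x padded lateral grid.
#' @return real nonnegative array \code{[z, y, x]} summing to 1, centered
#'   at the volume center.
#' @examples
#' psf <- computePSF(acquisitionGeometry(), c(8, 32, 32))
#' sum(psf)
#' @export
computePSF <- function(geometry, shape, dxy = geometry@dxy, dz = geometry@dz) {
  stopifnot(length(shape) == 3L)
  if (any(shape < 4L)) stop("PSF grid must be at least 4 samples per dimension")
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  lem <- geometry@lambdaEm
  if (dxy > lem / (4 * geometry@na))
    warning(sprintf(
      "lateral sampling %.3g nm coarser than lambda_em/(4 NA) = %.3g nm; OTF support will alias",
      dxy, lem / (4 * geometry@na)))
  kx <- centeredFreqs(nx) / dxy
  ky <- centeredFreqs(ny) / dxy
  kr2 <- outer(ky^2, kx^2, `+`)
  pupil <- kr2 <= (geometry@na / lem)^2
  kzProp <- sqrt(pmax((geometry@nImmersion / lem)^2 - kr2, 0))
  zc <- centeredCoords(nz) * dz
  psf <- array(0, c(nz, ny, nx))
  for (iz in seq_len(nz)) {
    fk <- pupil * exp(2i * pi * zc[iz] * kzProp)
    f <- fftShift(stats::fft(ifftShift(fk), inverse = TRUE)) / length(fk)
    psf[iz, , ] <- Re(f * Conj(f))
  }
  psf / sum(psf)
}

#' Widefield OTF from a PSF
#'
#' 3-D discrete Fourier transform of the PSF, DC-centered and normalised
#' so the DC value is 1.  For the scalar pupil model the lateral energy
#' per z-plane is constant, so the OTF vanishes identically on the axial
#' frequency axis away from DC -- the missing cone.
#'
#' @param psf real 3-D PSF array (from \code{\link{computePSF}}).
#' @param geometry the generating \linkS4class{AcquisitionGeometry}.
#' @return an \linkS4class{OTF3D}.
#' @export
psfToOTF <- function(psf, geometry) {
  if (all(psf == 0)) stop("all-zero PSF")
  ov <- ftn(psf)
  d <- dim(ov)
  dc <- ov[floor(d[1L] / 2) + 1L, floor(d[2L] / 2) + 1L, floor(d[3L] / 2) + 1L]
  new("OTF3D",
      values = ov / dc,
      kCutoffLateral = 2 * geometry@na / geometry@lambdaEm,
      kCutoffAxial = (geometry@nImmersion -
                        sqrt(geometry@nImmersion^2 - geometry@na^2)) / geometry@lambdaEm,
      geometry = geometry)
}

#' Band transfer function on the padded reconstruction grid
#'
#' Embeds the widefield OTF into the 2x laterally padded grid and, for the
#' first-order bands, averages two copies axially displaced by
#' \eqn{\pm q_z}: three-beam interference places first-order object
#' information at two axial side lobes, so the order +/-1 transfer
#' function has support at \eqn{(\pm q_z, 0, 0)} -- inside the widefield
#' missing cone.  Orders 0 and +/-2 use a plain embedded copy.
#'
#' @param otf an \linkS4class{OTF3D}.
#' @param order band order in \code{-2:2}.
#' @param axialShift \eqn{q_z} in cycles per z-step; required nonzero for
#'   \code{|order| == 1}, must be 0 otherwise.
#' @param padFactor lateral padding factor of the reconstruction grid.
#' @return complex 3-D array on the \code{(nz, padFactor*ny, padFactor*nx)}
#'   grid.
#' @export
bandOTF <- function(otf, order, axialShift = 0, padFactor = 2L) {
  stopifnot(order %in% -2:2)
  d <- dim(otf@values)
  if (abs(axialShift) > 0.5)
    stop("axial shift beyond the axial Nyquist (0.5 cycles per z-step)")
  E <- embedLateral(otf@values, padFactor * d[2L], padFactor * d[3L])
  if (abs(order) == 1L) {
    (shiftSpectrum(E, c(axialShift, 0, 0)) +
       shiftSpectrum(E, c(-axialShift, 0, 0))) / 2
  } else {
    if (axialShift != 0)
      stop("axialShift must be 0 for orders 0 and +/-2")
    E
  }
}
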