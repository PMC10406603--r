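#' Phase-separation matrix and its pseudo-inverse
#'
#' Each raw image of a phase series mixes the five illumination orders as
#' \eqn{D_p = \sum_m B_m e^{i m \phi_p}}.  The forward mixing matrix is
#' \code{M[p, m] = exp(1i * m * phi_p)} for \eqn{m = -2..2}; its left
#' pseudo-inverse unmixes the bands.  For five equally spaced phases
#' \eqn{\phi_p = 2\pi p/5} the columns are orthogonal and the
#' pseudo-inverse reduces to \eqn{M^H/5}.
#'
#' @param phases numeric vector of at least 5 phase offsets, rad,
#'   distinct modulo \eqn{2\pi}.
#' @return list with elements \code{M} (P x 5 complex), \code{pinv}
#'   (5 x P complex) and \code{phases}.
#' @examples
#' sep <- separationMatrix(2 * pi * (0:4) / 5)
#' round(Mod(sep$pinv %*% sep$M), 10)   # identity
#' @export
separationMatrix <- function(phases) {
  P <- length(phases)
  if (P < 5L) stop("need at least 5 phases to separate 5 bands")
  orders <- -2:2
  M <- outer(phases, orders, function(p, m) exp(1i * m * p))
  sv <- svd(M)$d
  if (min(sv) < 1e-10 * max(sv))
    stop("singular phase set: phases do not separate the five bands ",
         "(rank of the separation matrix < 5)")
  Mh <- Conj(t(M))
  pinv <- solve(Mh %*% M, Mh)
  list(M = M, pinv = pinv, phases = phases)
}

#' Separate the five frequency bands of one pattern angle
#'
#' Applies a lateral Tukey taper to every plane, takes the 3-D Fourier
#' transform of each phase-stepped volume (the full z-stack at once --
#' required for the axial band structure), and unmixes the five bands by
#' applying the phase-matrix pseudo-inverse across the phase axis,
#' pixel-wise in frequency space.
#'
#' With real input images the bands obey conjugate symmetry:
#' band \eqn{-m} equals the complex conjugate of band \eqn{+m} mirrored
#' through the frequency origin.
#'
#' @param stackAngle real 4-D array \code{[phase, z, y, x]} of one angle.
#' @param phases phase offsets, rad; must match the first extent.
#' @param taperAlpha Tukey window fraction applied in x and y per plane
#'   (0 disables; default 0.1 suppresses spectral leakage that would
#'   masquerade as stripe artifacts).
#' @param geometry the \linkS4class{AcquisitionGeometry}.
#' @param angleIndex which pattern angle this is (bookkeeping).
#' @return a \linkS4class{BandSet}.
#' @export
separateBands <- function(stackAngle, phases, taperAlpha = 0.1,
                          geometry, angleIndex = 1L) {
  d <- dim(stackAngle)
  if (length(d) != 4L) stop("stackAngle must be [phase, z, y, x]")
  if (d[1L] != length(phases))
    stop(sprintf("phase count mismatch: %d phase images but %d phases given",
                 d[1L], length(phases)))
  sep <- separationMatrix(phases)
  spectra <- vector("list", d[1L])
  for (p in seq_len(d[1L])) {
    vol <- array(stackAngle[p, , , ], d[2:4])
    spectra[[p]] <- ftn(taperLateral(vol, taperAlpha))
  }
  orders <- -2:2
  bandList <- vector("list", 5L)
  for (mi in seq_along(orders)) {
    acc <- array(0 + 0i, d[2:4])
    for (p in seq_len(d[1L]))
      acc <- acc + sep$pinv[mi, p] * spectra[[p]]
    bandList[[mi]] <- acc
  }
  names(bandList) <- as.character(orders)
  new("BandSet", bands = bandList, angleIndex = as.integer(angleIndex),
      geometry = geometry)
}
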