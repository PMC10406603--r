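# Pattern-parameter estimation by cross-correlation.
#
# The correlation between band 0 and a moved band m over all lateral
# shifts is computed with the Fourier trick: if i0 and im are the
# real-space fields of the two (OTF-weighted) band spectra, then
#   C(k) = sum_r im(r) conj(i0(r)) exp(-2i pi k.r_lat)
# is the lateral transform of the z-summed pointwise product, and it
# peaks at the pattern frequency (m.p laterally).  Under scanned
# three-beam acquisition every band carries a single object copy (the
# first-order axial side lobes live in the band transfer function, not
# in the data's carrier), so a plain z-sum is the matched collapse for
# all orders.

.otfWeight <- function(otf, reg = 0.15) {
  m <- Mod(otf@values)
  m / (m^2 + reg^2)
}

.ft2 <- function(m) fftShift(stats::fft(ifftShift(m)))

#' Cross-correlation surface between two bands
#'
#' Correlates \code{bandMoved} against \code{bandRef} over all lateral
#' frequency shifts, after weighting both spectra by the OTF common
#' support (a Wiener-like flattening that equalises the passband without
#' amplifying frequencies the system never measured).
#'
#' @param bandRef,bandMoved complex DC-centered spectra of the same angle
#'   (typically band 0 and band +1 or +2).
#' @param otf the \linkS4class{OTF3D} used for support weighting.
#' @param weightReg regularisation of the OTF weighting.
#' @return object of class \code{simCorrelation}: a list with
#'   \code{surface} (complex 2-D lateral correlation over all integer
#'   frequency-bin shifts), \code{magnitude} (its modulus) and \code{q}
#'   (the real-space product field, kept for zoomed refinement).
#' @export
crossCorrelationMap <- function(bandRef, bandMoved, otf, weightReg = 0.15) {
  if (!identical(dim(bandRef), dim(bandMoved)))
    stop("bands must share one grid")
  w <- .otfWeight(otf, weightReg)
  i0 <- iftn(bandRef * w)
  im <- iftn(bandMoved * w)
  .corrFromProduct(im * Conj(i0))
}

.corrFromProduct <- function(q) {
  d <- dim(q)
  qc <- matrix(0 + 0i, d[2L], d[3L])
  for (z in seq_len(d[1L])) qc <- qc + q[z, , ]
  surf <- .ft2(qc)
  structure(list(surface = surf, magnitude = Mod(surf), q = q),
            class = "simCorrelation")
}

# normalised passband overlap sum(W^2 O(k) O(k+shift)) / sum(W^2 |O|^2)
# for shift = c(kz, ky, kx) in cycles/sample
.overlapFactor <- function(otf, shift, reg = 0.15) {
  W <- .otfWeight(otf, reg)
  Osh <- shiftSpectrum(otf@values, shift)
  Mod(sum(W^2 * Conj(otf@values) * Osh)) / sum(W^2 * Mod(otf@values)^2)
}

# single zoomed evaluation of the correlation at lateral frequency
# k = c(ky, kx) cycles/px, with an axial demodulation weight
.corrValueAt <- function(q, ky, kx, zWeight = NULL) {
  d <- dim(q)
  if (is.null(zWeight)) zWeight <- rep(1, d[1L])
  qc <- matrix(0 + 0i, d[2L], d[3L])
  for (iz in seq_len(d[1L])) qc <- qc + zWeight[iz] * q[iz, , ]
  zoomDFT2(qc, ky, kx)[1L, 1L]
}

#' Locate the correlation peak with subpixel precision
#'
#' Two-stage search: integer argmax of the correlation magnitude
#' (optionally restricted to a search annulus), then a zoomed DFT
#' refinement of the real-space product field in a +/-1.5-bin
#' neighbourhood.  The reliability of the peak is summarised as the
#' contrast ratio: peak magnitude over the 99.5th-percentile magnitude
#' in a surrounding annulus (radii 5-15 bins, excluding the peak disc).
#' Normalising by a near-extreme rather than the median keeps the null
#' calibrated: the argmax of a featureless (pure-noise) surface is
#' itself an extreme value, so it scores ~1 here, while a genuine
#' carrier peak must rise above everything the background ever reaches.
#'
#' @param corr a \code{simCorrelation} from \code{\link{crossCorrelationMap}}.
#' @param upsample zoom factor of the subpixel refinement (>= 20 advised).
#' @param mask optional logical matrix restricting the integer search
#'   (e.g. a frequency annulus).
#' @param annulus radii (bins) of the contrast annulus.
#' @param excludeRadius peak disc excluded from the annulus.
#' @return list with \code{freq} (named c(kx, ky), cycles/px),
#'   \code{value} (complex correlation at the refined peak),
#'   \code{contrast}, and \code{kzFreq} (axial frequency of the dominant
#'   correlation plane, cycles per z-step).
#' @export
locatePeakSubpixel <- function(corr, upsample = 32L, mask = NULL,
                               annulus = c(5, 15), excludeRadius = 3) {
  M <- corr$magnitude
  d <- dim(M)
  # search on the prominence-normalised surface: divide by the radially
  # smooth background (median per radius ring about DC), so the broad
  # object self-correlation envelope around DC cannot outvote the sharp
  # carrier peak riding on it
  cy <- floor(d[1L] / 2) + 1L
  cx <- floor(d[2L] / 2) + 1L
  rr0 <- sqrt(outer((seq_len(d[1L]) - cy)^2, (seq_len(d[2L]) - cx)^2, `+`))
  ring <- pmin(round(rr0), max(cy, cx)) + 1L
  bg <- tapply(as.vector(M), as.vector(ring), stats::median)
  bg <- stats::filter(bg, rep(1 / 3, 3), sides = 2)
  bg[is.na(bg)] <- stats::median(M)
  bgMap <- matrix(pmax(as.numeric(bg)[ring], 1e-300), d[1L], d[2L])
  Ms <- M / bgMap
  if (!is.null(mask)) Ms[!mask] <- -Inf
  if (max(M) - min(M) <= 1e-12 * max(M))
    return(list(freq = c(kx = 0, ky = 0), value = complex(real = max(M)),
                contrast = 1))
  # ties broken deterministically towards the lexicographically smaller
  # (ky, kx) frequency
  cand <- which(Ms >= max(Ms) * (1 - 1e-9))
  if (length(cand) > 1L) {
    ci <- arrayInd(cand, d)
    fy <- centeredFreqs(d[1L])[ci[, 1L]]
    fx <- centeredFreqs(d[2L])[ci[, 2L]]
    cand <- cand[order(fy, fx)][1L]
  }
  imax <- arrayInd(cand[1L], d)
  iy <- imax[1L]; ix <- imax[2L]
  if (iy <= 1L || iy >= d[1L] || ix <= 1L || ix >= d[2L])
    stop("correlation maximum on the border of the search region; ",
         "widen the search annulus")
  # contrast ratio against the surrounding annulus
  ry <- outer(seq_len(d[1L]) - iy, rep(1, d[2L]))
  rx <- outer(rep(1, d[1L]), seq_len(d[2L]) - ix)
  rr <- sqrt(ry^2 + rx^2)
  ann <- rr >= annulus[1L] & rr <= annulus[2L] & rr > excludeRadius
  # normalise by a high annulus quantile rather than the median: the
  # argmax of a featureless surface is an extreme value sitting ~4x
  # above the median, so a median-normalised ratio would have its null
  # at the decision threshold; against the near-extreme background
  # level a featureless surface scores ~1
  lev <- stats::quantile(M[ann], 0.995, names = FALSE)
  contrast <- if (lev > 0) M[iy, ix] / lev else if (M[iy, ix] > 0) Inf else 1
  # zoomed refinement around the integer peak
  fy0 <- centeredFreqs(d[1L])[iy]
  fx0 <- centeredFreqs(d[2L])[ix]
  nzq <- dim(corr$q)[1L]
  qc <- matrix(0 + 0i, d[1L], d[2L])
  for (iz in seq_len(nzq)) qc <- qc + corr$q[iz, , ]
  binOffsets <- seq(-1.5, 1.5, by = 1 / upsample)
  ky <- fy0 + binOffsets / d[1L]
  kx <- fx0 + binOffsets / d[2L]
  Z <- zoomDFT2(qc, ky, kx)
  zi <- arrayInd(which.max(Mod(Z)), dim(Z))
  list(freq = c(kx = kx[zi[2L]], ky = ky[zi[1L]]),
       value = Z[zi[1L], zi[2L]],
       contrast = contrast)
}

.annulusMask <- function(d, lo, hi) {
  fy <- centeredFreqs(d[1L])
  fx <- centeredFreqs(d[2L])
  r <- sqrt(outer(fy^2, fx^2, `+`))
  r >= lo & r <= hi
}

#' Estimate illumination-pattern parameters for one angle
#'
#' Correlates band +2 against band 0; the peak sits at \eqn{2p} and is the
#' most accurate frequency reference when visible.  If its contrast ratio
#' falls below \code{rMin} -- which happens at low signal-to-noise, where
#' the first-order peak survives longer than the second -- the estimate
#' falls back to the band +1 peak at \eqn{p} (doubled to obtain the
#' second-order shift), flagged \code{FIRST_ORDER_FALLBACK}.  The initial
#' pattern phase is always read from the +1-band correlation evaluated at
#' the refined frequency with the geometric axial demodulation (the +2
#' correlation only carries \eqn{2\phi_0}, ambiguous by \eqn{\pi} when
#' halved); the axial frequency \eqn{q_z} follows from \eqn{|p|} and the
#' geometry (\code{\link{axialPatternFreq}}); modulation depths are the
#' correlation-to-autocorrelation ratios, clipped to \code{[mMin, 1]}.
#'
#' @param bandset a \linkS4class{BandSet}.
#' @param otf the \linkS4class{OTF3D}.
#' @param rMin reliability threshold on the +2 peak contrast ratio.
#' @param rMinFallback minimum contrast of the +1 peak; below it
#'   estimation fails with an error naming the angle.
#' @param searchAnnulus \code{c(lo, hi)} fractions of the lateral cutoff
#'   bracketing the second-order frequency \eqn{2|p|}.
#' @param upsample subpixel refinement factor.
#' @param mMin modulation-depth floor applied before Wiener weighting
#'   (avoids noise amplification by near-zero division).
#' @param freqOverride optional \code{c(kx, ky)} cycles/px: skip the
#'   frequency search and only estimate phase and depths.
#' @param forceFallback force the first-order path (diagnostics).
#' @return a \linkS4class{PatternParams}.
#' @export
estimatePattern <- function(bandset, otf, rMin = 4, rMinFallback = 2,
                            searchAnnulus = c(0.3, 1.1), upsample = 32L,
                            mMin = 0.15, freqOverride = NULL,
                            forceFallback = FALSE) {
  g <- bandset@geometry
  b <- bandset@bands
  kc <- lateralCutoff(g, "px")
  w <- .otfWeight(otf)
  i0 <- iftn(b[["0"]] * w)
  i1 <- iftn(b[["1"]] * w)
  i2 <- iftn(b[["2"]] * w)
  q1 <- i1 * Conj(i0)
  q2 <- i2 * Conj(i0)
  c2 <- .corrFromProduct(q2)
  c1 <- .corrFromProduct(q1)
  d2 <- dim(c2$magnitude)
  mask2 <- .annulusMask(d2, searchAnnulus[1L] * kc, searchAnnulus[2L] * kc)
  mask1 <- .annulusMask(d2, searchAnnulus[1L] * kc / 2, searchAnnulus[2L] * kc / 2)
  pk2 <- tryCatch(locatePeakSubpixel(c2, upsample, mask2),
                  error = function(e) list(contrast = 0))
  pk1 <- tryCatch(locatePeakSubpixel(c1, upsample, mask1),
                  error = function(e) list(contrast = 0))

  if (!is.null(freqOverride)) {
    p <- c(kx = freqOverride[1L], ky = freqOverride[2L])
    source <- "SECOND_ORDER"
    reliability <- pk2$contrast
  } else if (!forceFallback && pk2$contrast >= rMin) {
    p <- pk2$freq / 2
    source <- "SECOND_ORDER"
    reliability <- pk2$contrast
  } else if (pk1$contrast >= rMinFallback) {
    p <- pk1$freq
    source <- "FIRST_ORDER_FALLBACK"
    reliability <- pk1$contrast
  } else {
    stop(sprintf(
      "pattern estimation failed for angle %d: +2 peak contrast %.2f < %.2f and +1 peak contrast %.2f < %.2f",
      bandset@angleIndex, pk2$contrast, rMin, pk1$contrast, rMinFallback))
  }

  qz <- axialPatternFreq(g, sqrt(sum(p^2)))
  C1 <- .corrValueAt(q1, p["ky"], p["kx"])
  C2 <- .corrValueAt(q2, 2 * p["ky"], 2 * p["kx"])
  A0 <- sum(Mod(i0)^2)
  phi0 <- Arg(C1) %% (2 * pi)
  # the raw correlation-to-autocorrelation ratio absorbs the passband
  # overlap between the shifted and unshifted OTFs; divide it out (it is
  # fully determined by the OTF and the estimated frequency) so the
  # depths land on the illumination-coefficient scale; the first-order
  # overlap averages the two axial lobes of the band transfer function
  f1 <- max((.overlapFactor(otf, c(qz, p["ky"], p["kx"])) +
               .overlapFactor(otf, c(-qz, p["ky"], p["kx"]))) / 2, 0.02)
  f2 <- max(.overlapFactor(otf, c(0, 2 * p["ky"], 2 * p["kx"])), 0.02)
  m1raw <- 2 * Mod(C1) / A0 / f1
  m2raw <- 2 * Mod(C2) / A0 / f2
  clip <- c(m1 = m1raw < mMin || m1raw > 1, m2 = m2raw < mMin || m2raw > 1)
  m1 <- min(max(m1raw, mMin), 1)
  m2 <- min(max(m2raw, mMin), 1)
  if (any(clip))
    message(sprintf(
      "angle %d: modulation depth clipped to [%.2f, 1] (raw m1 = %.3f, m2 = %.3f)",
      bandset@angleIndex, mMin, m1raw, m2raw))
  new("PatternParams", p = unname(p), qz = qz, phi0 = phi0,
      m1 = m1, m2 = m2, source = source, reliability = reliability,
      depthClipped = unname(clip))
}
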