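# Centered discrete Fourier conventions used throughout the package.
#
# All spectra are DC-centered: the zero-frequency sample sits at index
# floor(n/2)+1 along every dimension.  Real-space arrays use the matching
# centered coordinate (0 at index floor(n/2)+1), so a symmetric PSF is
# even about the array center and its transform is real.

fftShiftIdx <- function(n) {
  if (n == 1L) return(1L)
  h <- ceiling(n / 2)
  c((h + 1L):n, 1L:h)
}

ifftShiftIdx <- function(n) {
  if (n == 1L) return(1L)
  h <- floor(n / 2)
  c((h + 1L):n, 1L:h)
}

arrPerm <- function(x, f) {
  d <- dim(x)
  if (is.null(d)) return(x[f(length(x))])
  idx <- lapply(d, f)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

fftShift <- function(x) arrPerm(x, fftShiftIdx)
ifftShift <- function(x) arrPerm(x, ifftShiftIdx)

# forward / inverse n-dimensional transforms, centered in both domains
ftn <- function(x) fftShift(stats::fft(ifftShift(x)))
iftn <- function(X) fftShift(stats::fft(ifftShift(X), inverse = TRUE)) / length(X)

# centered sample coordinates (0 at the DC index) and frequencies (cycles/sample)
centeredCoords <- function(n) seq_len(n) - 1L - floor(n / 2)
centeredFreqs <- function(n) centeredCoords(n) / n

# three full coordinate arrays for a (nz, ny, nx) volume
grid3 <- function(vz, vy, vx) {
  nz <- length(vz); ny <- length(vy); nx <- length(vx)
  list(
    z = array(vz, c(nz, ny, nx)),
    y = array(rep(vy, each = nz), c(nz, ny, nx)),
    x = array(rep(vx, each = nz * ny), c(nz, ny, nx))
  )
}

# embed a DC-centered (nz, ny, nx) spectrum into a larger DC-centered
# (nz, py, px) grid, zero-padding the lateral high frequencies
embedLateral <- function(spec, py, px) {
  d <- dim(spec)
  out <- array(0 + 0i, c(d[1L], py, px))
  oy <- floor(py / 2) - floor(d[2L] / 2)
  ox <- floor(px / 2) - floor(d[3L] / 2)
  out[, oy + seq_len(d[2L]), ox + seq_len(d[3L])] <- spec
  out
}

# S'(k) = S(k + shift), shift in cycles/sample per dimension (z, y, x);
# exact subpixel translation via a real-space phase ramp
shiftSpectrum <- function(spec, shift) {
  if (all(shift == 0)) return(spec)
  d <- dim(spec)
  g <- grid3(centeredCoords(d[1L]), centeredCoords(d[2L]), centeredCoords(d[3L]))
  s <- iftn(spec)
  s <- s * exp(-2i * pi * (shift[1L] * g$z + shift[2L] * g$y + shift[3L] * g$x))
  ftn(s)
}

# zero the unpaired -Nyquist planes (index 1 along even-length axes) of a
# DC-centered spectrum; they have no +Nyquist partner, so any content there
# breaks conjugate symmetry after shifting.  For band-limited data they sit
# beyond the OTF support and carry no signal.
zeroNyquist <- function(spec) {
  d <- dim(spec)
  if (d[1L] %% 2L == 0L) spec[1L, , ] <- 0
  if (d[2L] %% 2L == 0L) spec[, 1L, ] <- 0
  if (d[3L] %% 2L == 0L) spec[, , 1L] <- 0
  spec
}

# index map sending frequency k to -k on a DC-centered grid
# (the unpaired -Nyquist sample of an even-length axis maps to itself)
conjMirrorIdx <- function(n) {
  if (n == 1L) return(1L)
  c(1L, n:2L)
}

conjMirror <- function(x) Conj(arrPerm(x, conjMirrorIdx))

# Tukey (tapered cosine) window; alpha is the total fraction of the
# window inside the two cosine lobes
tukeyWindow <- function(n, alpha = 0.1) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# apply a lateral Tukey taper to every z-plane of a (nz, ny, nx) volume
taperLateral <- function(vol, alpha = 0.1) {
  if (alpha <= 0) return(vol)
  d <- dim(vol)
  w <- outer(tukeyWindow(d[2L], alpha), tukeyWindow(d[3L], alpha))
  vol * array(rep(w, each = d[1L]), d)
}

# zoomed 2-D DFT: evaluate C(ky, kx) = sum_{y,x} q[y,x] exp(-2i*pi*(ky*yc + kx*xc))
# on an arbitrary fine frequency grid (centered coordinates), by matrix products
zoomDFT2 <- function(q, ky, kx) {
  yc <- centeredCoords(nrow(q))
  xc <- centeredCoords(ncol(q))
  Ey <- exp(-2i * pi * outer(ky, yc))
  Ex <- exp(-2i * pi * outer(xc, kx))
  Ey %*% q %*% Ex
}

# lateral radial average of a 2-D magnitude image about its DC-centered origin
radialProfile <- function(mag, binWidth = 1) {
  d <- dim(mag)
  r <- sqrt(outer(centeredCoords(d[1L])^2, centeredCoords(d[2L])^2, `+`))
  bin <- floor(r / binWidth)
  means <- tapply(as.vector(mag), as.vector(bin), mean)
  list(radius = (as.numeric(names(means)) + 0.5) * binWidth, value = unname(means))
}
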