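#' @import methods
NULL

#' Acquisition geometry of a 3D-SIM dataset
#'
#' Describes the optical and sampling parameters of a structured
#' illumination acquisition: the number of pattern angles and phase steps,
#' excitation/emission wavelengths, objective numerical aperture, immersion
#' index, pixel pitch, and the on-disk dimension ordering of the raw TIFF.
#'
#' A conforming three-beam acquisition records \code{nAngles * nPhases}
#' raw 2-D images per z-plane (15 for the standard 3 angles x 5 phases).
#' Five phase steps are the minimum because the illumination mixes five
#' frequency bands (orders 0, +/-1, +/-2) into every raw image.
#'
#' @slot nAngles integer, number of pattern orientations (>= 1).
#' @slot nPhases integer, number of phase steps per angle (>= 5).
#' @slot lambdaExc excitation wavelength in nm.
#' @slot lambdaEm emission wavelength in nm.
#' @slot na objective numerical aperture (must be < \code{nImmersion}).
#' @slot nImmersion immersion refractive index.
#' @slot dxy lateral pixel size in nm.
#' @slot dz axial step in nm.
#' @slot layout one of \code{"OMX"}, \code{"NSIM"}, \code{"HOMEBUILT"};
#'   see \code{\link{loadRawStack}} for the page orderings.
#'
#' @seealso \code{\link{acquisitionGeometry}} for the user constructor.
#' @export
setClass("AcquisitionGeometry",
  representation(
    nAngles = "integer", nPhases = "integer",
    lambdaExc = "numeric", lambdaEm = "numeric",
    na = "numeric", nImmersion = "numeric",
    dxy = "numeric", dz = "numeric",
    layout = "character"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msg <- character()
  if (object@nPhases < 5L)
    msg <- c(msg, "nPhases must be >= 5 (five bands require five phase steps)")
  if (object@nAngles < 1L)
    msg <- c(msg, "nAngles must be >= 1")
  if (!(object@na < object@nImmersion))
    msg <- c(msg, "numerical aperture must be smaller than the immersion index")
  lens <- c(object@lambdaExc, object@lambdaEm, object@dxy, object@dz)
  if (any(!is.finite(lens)) || any(lens <= 0))
    msg <- c(msg, "wavelengths and pixel sizes must be positive")
  if (!object@layout %in% c("OMX", "NSIM", "HOMEBUILT"))
    msg <- c(msg, "layout must be one of 'OMX', 'NSIM', 'HOMEBUILT'")
  if (length(msg)) msg else TRUE
})

#' Raw 3D-SIM stack in canonical order
#'
#' Holds the raw intensity data as a 5-D array indexed
#' \code{[angle, phase, z, y, x]} together with its
#' \linkS4class{AcquisitionGeometry}.  Loaders normalise all on-disk
#' layouts to this order, so downstream code never sees layout detail.
#'
#' @slot data numeric 5-D array, photon-count scale, \code{[a, p, z, y, x]}.
#' @slot geometry the \linkS4class{AcquisitionGeometry}.
#' @slot channelId,timeId which channel/timepoint of the source file this is.
#' @export
setClass("RawStack",
  representation(
    data = "array",
    geometry = "AcquisitionGeometry",
    channelId = "integer",
    timeId = "integer"
  )
)

setValidity("RawStack", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 5L)
    msg <- c(msg, "data must be a 5-D array [angle, phase, z, y, x]")
  else {
    if (d[1L] != object@geometry@nAngles)
      msg <- c(msg, sprintf("angle extent %d != geometry nAngles %d",
                            d[1L], object@geometry@nAngles))
    if (d[2L] != object@geometry@nPhases)
      msg <- c(msg, sprintf("phase extent %d != geometry nPhases %d",
                            d[2L], object@geometry@nPhases))
    if (d[3L] < 1L) msg <- c(msg, "z extent must be >= 1")
  }
  if (length(msg)) msg else TRUE
})

#' Widefield 3-D optical transfer function
#'
#' DC-centered complex OTF on the acquisition grid, normalised to 1 at DC,
#' together with the theoretical lateral and axial support cutoffs.  The
#' widefield 3-D OTF vanishes on the axial frequency axis away from DC
#' (the "missing cone"), which is what destroys optical sectioning in a
#' conventional image and what the shifted first-order bands restore.
#'
#' @slot values complex 3-D array \code{[kz, ky, kx]}, DC-centered.
#' @slot kCutoffLateral lateral support cutoff \code{2 NA / lambda_em}, cycles/nm.
#' @slot kCutoffAxial axial cutoff
#'   \code{(n - sqrt(n^2 - NA^2)) / lambda_em}, cycles/nm.
#' @slot geometry the generating \linkS4class{AcquisitionGeometry}.
#' @export
setClass("OTF3D",
  representation(
    values = "array",
    kCutoffLateral = "numeric",
    kCutoffAxial = "numeric",
    geometry = "AcquisitionGeometry"
  )
)

#' Separated frequency bands of one pattern angle
#'
#' The five complex spectra (orders -2..+2) obtained by applying the
#' phase-separation matrix across the phase-stepped images of one angle.
#' Bands are DC-centered on the acquisition grid; the order-m band carries
#' object spectrum displaced by m times the pattern frequency.
#'
#' @slot bands named list of five complex 3-D arrays, names
#'   \code{"-2","-1","0","1","2"}.
#' @slot angleIndex which pattern angle these bands belong to.
#' @slot geometry the \linkS4class{AcquisitionGeometry}.
#' @export
setClass("BandSet",
  representation(
    bands = "list",
    angleIndex = "integer",
    geometry = "AcquisitionGeometry"
  )
)

setValidity("BandSet", function(object) {
  if (!identical(names(object@bands), c("-2", "-1", "0", "1", "2")))
    return("bands must be a named list with orders '-2','-1','0','1','2'")
  TRUE
})

#' Estimated illumination-pattern parameters of one angle
#'
#' @slot p lateral pattern frequency vector \code{c(kx, ky)} in cycles per
#'   (original) pixel; the first-order band sits at \code{+/-p}, the second
#'   at \code{+/-2p}.
#' @slot qz axial pattern frequency in cycles per z-step, derived from
#'   \code{|p|} and the geometry (three-beam interference fixes it).
#' @slot phi0 initial pattern phase in rad, referenced to the volume center.
#' @slot m1,m2 effective first/second-order modulation depths on the
#'   illumination-coefficient scale, clipped to \code{[mMin, 1]}.
#' @slot source \code{"SECOND_ORDER"} when the +2 correlation peak passed
#'   the reliability criterion, \code{"FIRST_ORDER_FALLBACK"} otherwise.
#' @slot reliability peak-contrast ratio of the correlation peak actually
#'   used (peak magnitude over surrounding annulus median).
#' @slot depthClipped logical flags recording whether m1/m2 hit the floor
#'   or ceiling.
#' @export
setClass("PatternParams",
  representation(
    p = "numeric", qz = "numeric", phi0 = "numeric",
    m1 = "numeric", m2 = "numeric",
    source = "character", reliability = "numeric",
    depthClipped = "logical"
  )
)

setValidity("PatternParams", function(object) {
  if (!object@source %in% c("SECOND_ORDER", "FIRST_ORDER_FALLBACK"))
    return("source must be 'SECOND_ORDER' or 'FIRST_ORDER_FALLBACK'")
  if (length(object@p) != 2L) return("p must be c(kx, ky)")
  TRUE
})

#' Two-step spectral filter settings
#'
#' Parameters of the notch (Filter 1) and apodization (Filter 2) stages.
#' The notch is a product of inverted Gaussians centered on DC and on the
#' pattern peaks; it attenuates the band OTFs inside the Wiener numerator
#' so residual illumination peaks are suppressed.  The apodization is a
#' generalized-ellipsoid power roll-off applied once to the assembled
#' spectrum to prevent ringing from the hard support edge.
#'
#' @slot notchDepthDC,notchDepthP attenuation depths in \code{[0, 1)} at DC
#'   and at the pattern-frequency centers.
#' @slot notchSigma Gaussian width in cycles/pixel; \code{NA} means
#'   2 frequency samples of the input image (\code{2 / N}).
#' @slot wienerW Wiener regularisation on the OTF-normalised scale.
#' @slot apoGamma apodization sharpness exponent (> 0).
#' @slot apoCutoffLateral,apoCutoffAxial extended-support cutoffs in
#'   cycles/pixel; \code{NA} means derive from the estimated pattern
#'   (lateral \code{k_c + |2p|}, axial \code{k_{c,z} + q_z}, clamped to the
#'   grid Nyquist).
#' @slot notchEnabled disable Filter 1 entirely (diagnostics).
#' @export
setClass("FilterSpec",
  representation(
    notchDepthDC = "numeric", notchDepthP = "numeric", notchSigma = "numeric",
    wienerW = "numeric", apoGamma = "numeric",
    apoCutoffLateral = "numeric", apoCutoffAxial = "numeric",
    notchEnabled = "logical"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (object@notchDepthDC < 0 || object@notchDepthDC >= 1 ||
      object@notchDepthP < 0 || object@notchDepthP >= 1)
    msg <- c(msg, "notch depths must lie in [0, 1)")
  if (!is.na(object@notchSigma) && object@notchSigma <= 0)
    msg <- c(msg, "notchSigma must be positive")
  if (object@apoGamma <= 0) msg <- c(msg, "apoGamma must be > 0")
  if (object@wienerW < 0) msg <- c(msg, "wienerW must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Assembled super-resolution spectrum
#'
#' The generalized-Wiener combination of all shifted bands on the 2x
#' laterally padded grid, before the inverse transform.
#'
#' @slot values complex 3-D array \code{[kz, ky, kx]}, DC-centered, on the
#'   padded grid.
#' @slot effectiveSupport logical array marking where at least one shifted
#'   band OTF has appreciable magnitude.
#' @slot provenance list of the per-band weights and filter settings used.
#' @export
setClass("AssembledSpectrum",
  representation(
    values = "array",
    effectiveSupport = "array",
    provenance = "list"
  )
)

#' Reconstructed super-resolution volume
#'
#' Real 3-D volume \code{[z, y, x]} with lateral sampling halved (2x pixel
#' upsampling in x and y; z sampling unchanged), plus a provenance record
#' sufficient to re-run the reconstruction.
#'
#' @slot volume real 3-D array.
#' @slot geometry acquisition geometry of the input.
#' @slot provenance list: estimated pattern parameters, filter settings,
#'   validation warnings, negative-clip fraction, package version.
#' @export
setClass("Reconstruction",
  representation(
    volume = "array",
    geometry = "AcquisitionGeometry",
    provenance = "list"
  )
)

setValidity("Reconstruction", function(object) {
  if (!all(is.finite(object@volume))) return("volume must be finite everywhere")
  ind <- object@provenance$inputDim
  if (!is.null(ind)) {
    d <- dim(object@volume)
    if (d[2L] != 2L * ind[2L] || d[3L] != 2L * ind[3L])
      return("lateral output dimensions must be exactly 2x the input plane")
  }
  TRUE
})

#' Illumination nonuniformity calibration ratios
#'
#' Smooth per-pixel intensity ratios between the three pattern angles,
#' built from bead calibration fields: \code{calib1 = calib_ang2 /
#' calib_ang1} and \code{calib2 = calib_ang3 / calib_ang1}.
#'
#' @slot calib1,calib2 numeric matrices of ratios.
#' @slot mask logical matrix, TRUE where bead coverage supports the ratio.
#' @export
setClass("CalibrationRatios",
  representation(calib1 = "matrix", calib2 = "matrix", mask = "matrix")
)

#' Per-pixel fluorescent dipole orientation map
#'
#' @slot theta in-plane dipole orientation in rad, in \code{[0, pi)};
#'   meaningful only where \code{mask} is TRUE.
#' @slot amplitude polarization modulation amplitude (intensity units).
#' @slot dc mean intensity across the excitation orientations.
#' @slot mask logical; FALSE where the modulation is too weak to carry an
#'   angle.
#' @export
setClass("OrientationMap",
  representation(
    theta = "matrix", amplitude = "matrix",
    dc = "matrix", mask = "matrix"
  )
)

#' Forward-simulation configuration
#'
#' Study conditions for the three-beam interference simulator.  The
#' lateral pattern scale is given as the fraction of the detection cutoff
#' reached by the finest illumination component: \code{2|p| =
#' patternFreqFraction * k_cutoff}, so the first-order frequency is
#' \code{|p| = patternFreqFraction * k_cutoff / 2}.  Modulation depths
#' default to the exact three-beam values for the default center:side
#' amplitude ratio \code{2 + sqrt(2)} (the smallest ratio whose first-order
#' depth does not exceed 1): \code{m1 = 1}, \code{m2 = 1/(2R)}.
#'
#' @slot geometry acquisition geometry to emulate.
#' @slot patternFreqFraction \code{2|p| / k_cutoff}, in \code{(0, 1.2]}.
#' @slot patternAngles pattern azimuths in rad.
#' @slot phi0 initial pattern phase per angle, rad.
#' @slot modulationM1,modulationM2 illumination modulation depths in [0,1].
#' @slot peakPhotons expected photon count at the brightest pixel.
#' @slot readNoiseSd Gaussian read noise sd, photons.
#' @slot seed RNG seed; all simulator randomness derives from it.
#' @slot phantom one of \code{"beads"}, \code{"filaments"},
#'   \code{"sheet_z"}, \code{"uniform"}.
#' @export
setClass("SimConfig",
  representation(
    geometry = "AcquisitionGeometry",
    patternFreqFraction = "numeric",
    patternAngles = "numeric",
    phi0 = "numeric",
    modulationM1 = "numeric", modulationM2 = "numeric",
    peakPhotons = "numeric", readNoiseSd = "numeric",
    seed = "integer", phantom = "character"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@patternFreqFraction <= 0 || object@patternFreqFraction > 1.2)
    msg <- c(msg, "patternFreqFraction must lie in (0, 1.2]")
  if (object@modulationM1 < 0 || object@modulationM1 > 1 ||
      object@modulationM2 < 0 || object@modulationM2 > 1)
    msg <- c(msg, "modulation depths must lie in [0, 1]")
  if (length(object@phi0) != length(object@patternAngles))
    msg <- c(msg, "phi0 must have one entry per pattern angle")
  if (!object@phantom %in% c("beads", "filaments", "sheet_z", "uniform"))
    msg <- c(msg, "unknown phantom kind")
  if (length(msg)) msg else TRUE
})

#' Ground-truth phantom
#'
#' @slot volume nonnegative real 3-D fluorophore density \code{[z, y, x]}.
#' @slot dipoleTheta optional per-voxel dipole azimuth (rad) for
#'   polarization phantoms, or NULL.
#' @slot meta list of phantom parameters (e.g. the z-modulation frequency
#'   of a \code{sheet_z} phantom).
#' @export
setClass("GroundTruth",
  representation(volume = "array", dipoleTheta = "ANY", meta = "list")
)

setValidity("GroundTruth", function(object) {
  if (any(object@volume < 0)) return("phantom density must be nonnegative")
  TRUE
})
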