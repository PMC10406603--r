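#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))

#' @rdname accessors
#' @export
setGeneric("rawData", function(object) standardGeneric("rawData"))

#' @rdname accessors
#' @export
setGeneric("bands", function(object) standardGeneric("bands"))

#' @rdname accessors
#' @export
setGeneric("otfValues", function(object) standardGeneric("otfValues"))

#' @rdname accessors
#' @export
setGeneric("reconVolume", function(object) standardGeneric("reconVolume"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' Accessors for the core data classes
#'
#' Small read-only accessors so user code never touches slots directly:
#' \code{geometry()} returns the \linkS4class{AcquisitionGeometry} of any
#' container, \code{rawData()} the 5-D array of a \linkS4class{RawStack},
#' \code{bands()} the named list of band spectra of a
#' \linkS4class{BandSet}, \code{otfValues()} the complex OTF array,
#' \code{reconVolume()} the real volume of a \linkS4class{Reconstruction},
#' and \code{provenance()} its parameter record.
#'
#' @param object the container.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geometry", "RawStack", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "BandSet", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "OTF3D", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "Reconstruction", function(object) object@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "SimConfig", function(object) object@geometry)

#' @rdname accessors
#' @export
setMethod("rawData", "RawStack", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("bands", "BandSet", function(object) object@bands)

#' @rdname accessors
#' @export
setMethod("otfValues", "OTF3D", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("reconVolume", "Reconstruction", function(object) object@volume)

#' @rdname accessors
#' @export
setMethod("provenance", "Reconstruction", function(object) object@provenance)

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry:", object@nAngles, "angles x", object@nPhases,
      "phases,", object@layout, "layout\n")
  cat(sprintf("  exc/em %g/%g nm, NA %.2f, n %.3f, pixels %g x %g nm (xy x z)\n",
              object@lambdaExc, object@lambdaEm, object@na,
              object@nImmersion, object@dxy, object@dz))
})

setMethod("show", "RawStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("RawStack [angle %d, phase %d, z %d, y %d, x %d], channel %d, time %d\n",
              d[1], d[2], d[3], d[4], d[5], object@channelId, object@timeId))
})

setMethod("show", "OTF3D", function(object) {
  d <- dim(object@values)
  g <- object@geometry
  cat(sprintf("OTF3D [kz %d, ky %d, kx %d]\n", d[1], d[2], d[3]))
  cat(sprintf("  lateral cutoff %.4g cycles/nm (%.3f cycles/px), axial %.4g cycles/nm (%.3f cycles/px)\n",
              object@kCutoffLateral, object@kCutoffLateral * g@dxy,
              object@kCutoffAxial, object@kCutoffAxial * g@dz))
})

setMethod("show", "BandSet", function(object) {
  d <- dim(object@bands[["0"]])
  cat(sprintf("BandSet: 5 bands (orders -2..+2), angle %d, grid [%d x %d x %d]\n",
              object@angleIndex, d[1], d[2], d[3]))
})

setMethod("show", "PatternParams", function(object) {
  cat(sprintf("PatternParams: p = (%.4f, %.4f) cycles/px (|p| = %.4f), qz = %.4f\n",
              object@p[1], object@p[2], sqrt(sum(object@p^2)), object@qz))
  cat(sprintf("  phi0 = %.3f rad, m1 = %.3f, m2 = %.3f, source = %s (contrast %.1f)\n",
              object@phi0, object@m1, object@m2, object@source, object@reliability))
})

setMethod("show", "Reconstruction", function(object) {
  d <- dim(object@volume)
  cat(sprintf("Reconstruction [z %d, y %d, x %d], pixel %g x %g nm\n",
              d[1], d[2], d[3], object@geometry@dxy / 2, object@geometry@dz))
  if (!is.null(object@provenance$clipFraction))
    cat(sprintf("  negative values clipped: %.3g%% of voxels\n",
                100 * object@provenance$clipFraction))
})

setMethod("show", "OrientationMap", function(object) {
  cat(sprintf("OrientationMap [%d x %d], %d%% of pixels carry a significant angle\n",
              nrow(object@theta), ncol(object@theta),
              round(100 * mean(object@mask))))
})
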