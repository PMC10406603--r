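# Raw-stack TIFF readers/writers for the three supported dimension
# orderings, plus validation and float32 volume output.
#
# Page-index conventions (0-based, single channel/time shown):
#   OMX       page = p + nP*(z + nZ*(ch + nC*(t + nT*a)))   (phase fastest,
#             then depth, channel, time, angle slowest)
#   HOMEBUILT page = p + nP*(a + nA*(z + nZ*(ch + nC*t)))
#   NSIM      one montage page per (z, ch, t), page = z + nZ*(ch + nC*t);
#             each page tiles angle in rows and phase in columns.

# read all pages as stored values: readTIFF normalises unsigned-integer
# samples into [0, 1], so those are scaled back using the per-page sample
# metadata; float pages come through unchanged
.readPages <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    info <- attributes(p)
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # drop extra samples per pixel
    bits <- info$bits.per.sample
    # all pages are unsigned integers normalised by readTIFF: 8/16-bit by
    # 2^bits - 1, 32-bit by 2^32; restore the raw counts
    if (!is.null(bits) && bits[1L] %in% c(8L, 16L))
      p <- round(p * (2^bits[1L] - 1))
    else if (!is.null(bits) && bits[1L] == 32L)
      p <- round(p * 2^32)
    p
  })
}

.pageIndex <- function(layout, a, p, z, ch, tt, nA, nP, nZ, nC, nT) {
  switch(layout,
    OMX = (p - 1L) + nP * ((z - 1L) + nZ * ((ch - 1L) + nC * ((tt - 1L) + nT * (a - 1L)))),
    HOMEBUILT = (p - 1L) + nP * ((a - 1L) + nA * ((z - 1L) + nZ * ((ch - 1L) + nC * (tt - 1L)))),
    stop("unsupported layout: ", layout)
  ) + 1L
}

#' Load a raw 3D-SIM stack from a multi-page TIFF
#'
#' Reads any of the three supported on-disk dimension orderings and
#' returns the data in canonical \code{[angle, phase, z, y, x]} order, so
#' no downstream code ever depends on the acquisition system's layout.
#' Pixel values within a page are never reordered; only the
#' page-to-(angle, phase, z) mapping differs between layouts.
#'
#' Supported layouts (set in the geometry):
#' \describe{
#'   \item{OMX}{one page per 2-D image; page order phase, depth, channel,
#'     time, then angle (phase fastest, angle slowest).}
#'   \item{NSIM}{one montage page per (depth, channel, time); each page
#'     tiles angle in rows and phase in columns.}
#'   \item{HOMEBUILT}{one page per image; page order phase, angle, depth,
#'     channel, then time.}
#' }
#'
#' Native .dv/.nd2 containers are not parsed; export such data to TIFF
#' first.
#'
#' @param path multi-page TIFF file.
#' @param geometry an \linkS4class{AcquisitionGeometry} (carries the
#'   layout and the angle/phase counts).
#' @param channel,timepoint which channel/timepoint to select when the
#'   file holds several.
#' @param nChannels,nTimes how many channels/timepoints the file holds.
#' @param cameraOffset constant camera offset subtracted from every pixel;
#'   results are clamped at 0 (negative intensities would break the
#'   photon-scale assumptions downstream).
#' @return a \linkS4class{RawStack}.
#' @export
loadRawStack <- function(path, geometry, channel = 1L, timepoint = 1L,
                         nChannels = 1L, nTimes = 1L, cameraOffset = 0) {
  if (grepl("\\.(dv|nd2)$", path, ignore.case = TRUE))
    stop("native .dv/.nd2 containers are not supported; export the data ",
         "to multi-page TIFF first")
  pages <- .readPages(path)
  nA <- geometry@nAngles; nP <- geometry@nPhases
  nC <- as.integer(nChannels); nT <- as.integer(nTimes)
  nPages <- length(pages)

  if (geometry@layout == "NSIM") {
    if (nPages %% (nC * nT) != 0L)
      stop(sprintf("layout mismatch: %d montage pages not divisible by %d channels x %d timepoints",
                   nPages, nC, nT))
    nZ <- nPages %/% (nC * nT)
    pg1 <- pages[[1L]]
    if (nrow(pg1) %% nA != 0L || ncol(pg1) %% nP != 0L)
      stop(sprintf("tiling error: montage %d x %d not divisible by the %d x %d (angle x phase) tile grid",
                   nrow(pg1), ncol(pg1), nA, nP))
    ny <- nrow(pg1) %/% nA
    nx <- ncol(pg1) %/% nP
    dat <- array(0, c(nA, nP, nZ, ny, nx))
    for (z in seq_len(nZ)) {
      pg <- pages[[(z - 1L) + nZ * ((channel - 1L) + nC * (timepoint - 1L)) + 1L]]
      for (a in seq_len(nA)) for (p in seq_len(nP))
        dat[a, p, z, , ] <- pg[(a - 1L) * ny + seq_len(ny),
                               (p - 1L) * nx + seq_len(nx)]
    }
  } else {
    per <- nA * nP * nC * nT
    if (nPages %% per != 0L)
      stop(sprintf("layout mismatch: %d pages not divisible by %d angles x %d phases x %d channels x %d timepoints = %d",
                   nPages, nA, nP, nC, nT, per))
    nZ <- nPages %/% per
    ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
    dat <- array(0, c(nA, nP, nZ, ny, nx))
    for (a in seq_len(nA)) for (p in seq_len(nP)) for (z in seq_len(nZ)) {
      idx <- .pageIndex(geometry@layout, a, p, z, channel, timepoint,
                        nA, nP, nZ, nC, nT)
      dat[a, p, z, , ] <- pages[[idx]]
    }
  }
  meta <- .readScale(path)
  if (!is.null(meta) && identical(meta$mode, "scaled32"))
    dat <- dat * (meta$scale / (2^32 - 1))
  if (cameraOffset != 0) dat <- pmax(dat - cameraOffset, 0)
  new("RawStack", data = dat, geometry = geometry,
      channelId = as.integer(channel), timeId = as.integer(timepoint))
}

#' Write a raw stack to TIFF in any of the three layouts
#'
#' Inverse of \code{\link{loadRawStack}}: serialises the canonical 5-D
#' array into the requested on-disk page ordering.  Integer-valued data
#' within the 16-bit range are stored as uint16 (bit-exact round trip);
#' anything else as 32-bit samples quantized on a power-of-two scale
#' (quantum ~5e-10 of the full range; write/read round trips are
#' bit-stable), with the scale recorded in a JSON sidecar.
#'
#' @param stack a \linkS4class{RawStack}.
#' @param path output TIFF path.
#' @param layout override the geometry's layout.
#' @return invisibly, \code{path}.
#' @export
writeRawStack <- function(stack, path, layout = stack@geometry@layout) {
  d <- dim(stack@data)
  nA <- d[1L]; nP <- d[2L]; nZ <- d[3L]; ny <- d[4L]; nx <- d[5L]
  if (layout == "NSIM") {
    pages <- vector("list", nZ)
    for (z in seq_len(nZ)) {
      pg <- matrix(0, nA * ny, nP * nx)
      for (a in seq_len(nA)) for (p in seq_len(nP))
        pg[(a - 1L) * ny + seq_len(ny), (p - 1L) * nx + seq_len(nx)] <-
          stack@data[a, p, z, , ]
      pages[[z]] <- pg
    }
  } else {
    pages <- vector("list", nA * nP * nZ)
    for (a in seq_len(nA)) for (p in seq_len(nP)) for (z in seq_len(nZ)) {
      idx <- .pageIndex(layout, a, p, z, 1L, 1L, nA, nP, nZ, 1L, 1L)
      pages[[idx]] <- matrix(stack@data[a, p, z, , ], ny, nx)
    }
  }
  .writePagesTIFF(pages, path, sidecar = list(layout = layout))
  invisible(path)
}

# uint16 when integral and in range, else 32-bit quantized with a
# power-of-two scale.  The TIFF writer truncates 32-bit samples, so each
# quantized count k is passed as (k + 0.5)/(2^32 - 1): truncation lands
# exactly on k and write/read round trips are bit-stable.  The quantum is
# scale/2^32 of the full range (~5e-10 relative), recorded in the sidecar.
.writePagesTIFF <- function(pages, path, sidecar = NULL) {
  allv <- unlist(lapply(pages, range))
  vmax <- max(allv); vmin <- min(allv)
  integral <- all(vapply(pages, function(p) all(p == round(p)), logical(1L)))
  if (integral && vmin >= 0 && vmax <= 65535) {
    tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                    bits.per.sample = 16L, compression = "none")
    scale <- 65535
    mode <- "uint16"
  } else {
    if (vmin < 0) stop("negative intensities cannot be serialised")
    scale <- if (vmax > 0) 2^(ceiling(log2(vmax)) + 1) else 1
    M <- 2^32 - 1
    tiff::writeTIFF(lapply(pages, function(p) (round(p / scale * M) + 0.5) / M),
                    path, bits.per.sample = 32L, compression = "none")
    mode <- "scaled32"
  }
  if (!is.null(sidecar)) {
    sidecar$scale <- scale
    sidecar$mode <- mode
    jsonlite::write_json(sidecar, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(scale = scale, mode = mode))
}

.readScale <- function(path) {
  sc <- paste0(path, ".json")
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
  else NULL
}

#' Validate a raw stack before reconstruction
#'
#' Produces a report rather than throwing: reconstruction proceeds on
#' warnings and aborts on errors.  Errors: wrong frame multiplicity,
#' non-finite pixels (located by angle/phase/z).  Warnings: fewer than 6
#' z-layers (multilayer reconstruction needs axial context; results
#' degrade below six planes), pixels at or above the saturation ceiling.
#'
#' @param stack a \linkS4class{RawStack}.
#' @param saturation dynamic-range ceiling for the saturation warning.
#' @return list with character vectors \code{errors} and \code{warnings}.
#' @export
validateStack <- function(stack, saturation = 65535) {
  errors <- character()
  warnings <- character()
  d <- dim(stack@data)
  g <- stack@geometry
  if (d[1L] * d[2L] != g@nAngles * g@nPhases)
    errors <- c(errors, sprintf(
      "frame multiplicity: %d images per plane, expected %d angles x %d phases = %d",
      d[1L] * d[2L], g@nAngles, g@nPhases, g@nAngles * g@nPhases))
  bad <- which(!is.finite(stack@data))
  if (length(bad)) {
    loc <- arrayInd(bad[1L], d)
    errors <- c(errors, sprintf(
      "non-finite pixel(s): first at angle %d, phase %d, z %d",
      loc[1L], loc[2L], loc[3L]))
  }
  if (d[3L] < 6L)
    warnings <- c(warnings, sprintf(
      "fewer than 6 z-layers (%d): multilayer reconstruction is degraded", d[3L]))
  nSat <- sum(stack@data >= saturation, na.rm = TRUE)
  if (nSat > 0L)
    warnings <- c(warnings, sprintf("%d saturated pixel(s) at or above %g",
                                    nSat, saturation))
  list(errors = errors, warnings = warnings)
}

#' Write a reconstructed volume as 32-bit TIFF
#'
#' One page per z-slice.  Pages are quantized on a power-of-two scale
#' into 32-bit samples (quantum ~5e-10 of the full intensity range), and
#' the scale together with the output pixel sizes (dxy/2 after the 2x
#' lateral upsampling, dz unchanged) is stored in a JSON sidecar next to
#' the file.  \code{\link{readVolume}} undoes the scaling, reproducing
#' the stored quantized values bit-exactly.
#'
#' @param recon a \linkS4class{Reconstruction} (or a bare 3-D array).
#' @param path output path.
#' @param geometry required when \code{recon} is a bare array.
#' @return invisibly, \code{path}.
#' @export
writeVolume <- function(recon, path, geometry = NULL) {
  if (is(recon, "Reconstruction")) {
    vol <- recon@volume
    g <- recon@geometry
    prov <- recon@provenance
  } else {
    vol <- recon
    g <- geometry
    prov <- NULL
  }
  if (!all(is.finite(vol))) stop("volume must be finite")
  d <- dim(vol)
  pages <- lapply(seq_len(d[1L]), function(z) matrix(vol[z, , ], d[2L], d[3L]))
  sidecar <- list(dxy_nm = if (!is.null(g)) g@dxy / 2 else NA,
                  dz_nm = if (!is.null(g)) g@dz else NA,
                  nz = d[1L])
  if (!is.null(prov)) sidecar$provenance <- prov
  .writePagesTIFF(pages, path, sidecar)
  invisible(path)
}

#' Read a volume written by \code{\link{writeVolume}}
#'
#' @param path TIFF path (the JSON sidecar, if present, supplies the
#'   intensity scale and pixel sizes).
#' @return real 3-D array \code{[z, y, x]}; pixel sizes, when known, are
#'   attached as the \code{"pixelSize"} attribute.
#' @export
readVolume <- function(path) {
  pages <- .readPages(path)
  meta <- .readScale(path)
  # uint16 pages are read as raw counts; 32-bit pages are quantized counts
  scale <- if (!is.null(meta) && identical(meta$mode, "scaled32"))
    meta$scale / (2^32 - 1) else 1
  d <- c(length(pages), dim(pages[[1L]]))
  vol <- array(0, d)
  for (z in seq_len(d[1L])) vol[z, , ] <- pages[[z]] * scale
  if (!is.null(meta))
    attr(vol, "pixelSize") <- c(dxy = meta$dxy_nm, dz = meta$dz_nm)
  vol
}
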