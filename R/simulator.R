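#' Construct a simulation configuration
#'
#' The defaults are the study conditions used throughout the test suite:
#' OMX-like geometry, three pattern azimuths at 0/60/120 degrees, finest
#' illumination component at 0.8 of the detection cutoff
#' (\code{2|p| = 0.8 k_c}), three-beam modulation depths for a
#' center:side amplitude ratio of \eqn{2 + \sqrt 2} (\code{m1 = 1},
#' \code{m2 = 1/(2R) \approx 0.146}), 500 expected photons at the
#' brightest pixel and 1 photon rms read noise.
#'
#' @param geometry an \linkS4class{AcquisitionGeometry}.
#' @param patternFreqFraction \code{2|p| / k_cutoff}.
#' @param patternAngles pattern azimuths, rad.
#' @param phi0 initial pattern phase per angle, rad.
#' @param beamRatio center:side beam amplitude ratio; sets the default
#'   modulation depths \code{m1 = 4R/(R^2+2)}, \code{m2 = 2/(R^2+2)}.
#' @param modulationM1,modulationM2 explicit depth overrides in [0, 1].
#' @param peakPhotons expected photons at the brightest pixel.
#' @param readNoiseSd Gaussian read noise sd, photons.
#' @param seed integer seed for all simulator randomness.
#' @param phantom default phantom kind.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(geometry = acquisitionGeometry(),
                      patternFreqFraction = 0.8,
                      patternAngles = c(0, pi / 3, 2 * pi / 3),
                      phi0 = rep(0, length(patternAngles)),
                      beamRatio = 2 + sqrt(2),
                      modulationM1 = 4 * beamRatio / (beamRatio^2 + 2),
                      modulationM2 = 2 / (beamRatio^2 + 2),
                      peakPhotons = 500, readNoiseSd = 1,
                      seed = 1L, phantom = "filaments") {
  new("SimConfig", geometry = geometry,
      patternFreqFraction = patternFreqFraction,
      patternAngles = patternAngles, phi0 = phi0,
      modulationM1 = modulationM1, modulationM2 = modulationM2,
      peakPhotons = peakPhotons, readNoiseSd = readNoiseSd,
      seed = as.integer(seed), phantom = phantom)
}

#' Generate a ground-truth phantom
#'
#' Deterministic per seed.  Kinds:
#' \describe{
#'   \item{beads}{isolated sub-resolution points with a minimum pairwise
#'     separation; a single bead is placed at the volume center.}
#'   \item{filaments}{random smooth 3-D curves rasterised at ~1 px width.}
#'   \item{sheet_z}{uniform in x and y, raised-cosine modulated in z at
#'     \code{sheetFreq} cycles per z-step (recorded in \code{meta}).}
#'   \item{uniform}{constant density.}
#' }
#'
#' @param kind phantom kind.
#' @param shape \code{c(nz, ny, nx)}; at least \code{c(6, 64, 64)} for
#'   reconstruction-grade fixtures.
#' @param seed RNG seed.
#' @param nBeads,minSeparation bead count and minimum pairwise distance (px).
#' @param nFilaments curve count.
#' @param sheetFreq z-modulation frequency of \code{sheet_z}, cycles per
#'   z-step.
#' @param margin border kept empty, px.
#' @param background uniform fluorophore density added everywhere
#'   (fraction of the structure density); emulates the diffuse/defocused
#'   pedestal of real specimens.
#' @return a \linkS4class{GroundTruth}.
#' @export
makePhantom <- function(kind, shape, seed = 1L, nBeads = 12L,
                        minSeparation = 12, nFilaments = 20L,
                        sheetFreq = 0.1, margin = 8L, background = 0) {
  nz <- shape[1L]; ny <- shape[2L]; nx <- shape[3L]
  vol <- array(0, shape)
  meta <- list(kind = kind, seed = seed)
  withSeed <- function(expr) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    expr
  }
  if (kind == "uniform") {
    vol[] <- 1
  } else if (kind == "sheet_z") {
    zc <- centeredCoords(nz)
    prof <- 0.5 * (1 + cos(2 * pi * sheetFreq * zc))
    vol <- array(rep(prof, ny * nx), shape)
    meta$sheetFreq <- sheetFreq
  } else if (kind == "beads") {
    if (nBeads == 1L) {
      vol[floor(nz / 2) + 1L, floor(ny / 2) + 1L, floor(nx / 2) + 1L] <- 1
    } else {
      pos <- withSeed({
        acc <- matrix(numeric(0), 0, 3)
        tries <- 0L
        while (nrow(acc) < nBeads && tries < 5000L) {
          cand <- c(sample(seq(2L, nz - 1L), 1L),
                    sample(seq(margin, ny - margin), 1L),
                    sample(seq(margin, nx - margin), 1L))
          ok <- TRUE
          if (nrow(acc) > 0) {
            dd <- sqrt(colSums((t(acc[, 2:3, drop = FALSE]) - cand[2:3])^2))
            ok <- all(dd >= minSeparation)
          }
          if (ok) acc <- rbind(acc, cand)
          tries <- tries + 1L
        }
        acc
      })
      for (i in seq_len(nrow(pos)))
        vol[pos[i, 1L], pos[i, 2L], pos[i, 3L]] <- 1
      meta$positions <- pos
    }
  } else if (kind == "filaments") {
    # smooth random-walk curves, reflected at the field borders so each
    # filament keeps its full length (a dense network, as in a labelled
    # cytoskeleton, not a handful of short stubs)
    vol <- withSeed({
      v <- array(0, shape)
      lo <- c(1.5, margin, margin)
      hi <- c(nz - 0.5, ny - margin, nx - margin)
      for (f in seq_len(nFilaments)) {
        nSteps <- 6L * max(ny, nx)
        pos <- c(stats::runif(1, lo[1], hi[1]),
                 stats::runif(1, lo[2], hi[2]),
                 stats::runif(1, lo[3], hi[3]))
        dir <- stats::rnorm(3); dir[1] <- dir[1] * 0.15
        dir <- dir / sqrt(sum(dir^2))
        for (s in seq_len(nSteps)) {
          turn <- stats::rnorm(3, sd = 0.1); turn[1] <- turn[1] * 0.2
          dir <- dir + turn
          dir <- dir / sqrt(sum(dir^2))
          pos <- pos + dir * 0.5
          for (i in 1:3) {
            if (pos[i] < lo[i]) { pos[i] <- 2 * lo[i] - pos[i]; dir[i] <- -dir[i] }
            if (pos[i] > hi[i]) { pos[i] <- 2 * hi[i] - pos[i]; dir[i] <- -dir[i] }
          }
          v[round(pos[1]), round(pos[2]), round(pos[3])] <- 1
        }
      }
      v
    })
  } else {
    stop("unknown phantom kind: ", kind)
  }
  if (background > 0) {
    vol <- vol + background
    meta$background <- background
  }
  new("GroundTruth", volume = vol, dipoleTheta = NULL, meta = meta)
}

#' Three-beam structured illumination intensity pattern
#'
#' Interference of an axial center beam with two symmetric side beams
#' yields, after normalisation to unit mean,
#' \deqn{I(r) = 1 + m_1 \cos(2\pi q_z z)\cos\theta + m_2 \cos 2\theta,
#'   \quad \theta = 2\pi\, p \cdot r_{lat} + \phi}
#' with lateral Fourier content exactly at orders \{0, +/-1, +/-2\} and
#' first-order axial modulation at \eqn{\pm q_z}.  The phase of step
#' \code{phaseIndex} is \eqn{\phi_0 + 2\pi(\mathrm{phaseIndex}-1)/P}.
#' The spatial mean is independent of the phase step.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param angleIndex,phaseIndex which pattern angle and phase step.
#' @param dims \code{c(nz, ny, nx)} grid.
#' @return real nonnegative 3-D array.
#' @export
illuminationPattern <- function(config, angleIndex, phaseIndex, dims) {
  g <- config@geometry
  kc <- lateralCutoff(g, "px")
  pMag <- config@patternFreqFraction * kc / 2
  if (2 * pMag > 0.5)
    stop(sprintf("second-order pattern frequency %.3f cycles/px beyond the grid Nyquist",
                 2 * pMag))
  alpha <- config@patternAngles[angleIndex]
  pvec <- pMag * c(cos(alpha), sin(alpha))   # (kx, ky)
  qz <- axialPatternFreq(g, pMag)
  phi <- config@phi0[angleIndex] + 2 * pi * (phaseIndex - 1L) / g@nPhases
  gr <- grid3(centeredCoords(dims[1L]), centeredCoords(dims[2L]),
              centeredCoords(dims[3L]))
  theta <- 2 * pi * (pvec[1L] * gr$x + pvec[2L] * gr$y) + phi
  1 + config@modulationM1 * cos(2 * pi * qz * gr$z) * cos(theta) +
    config@modulationM2 * cos(2 * theta)
}

#' Simulate a raw 3D-SIM acquisition
#'
#' Scanned-acquisition forward model.  The interference pattern is locked
#' to the focal plane of the objective, so as the sample is stepped in z
#' the axial modulation travels with the focus: the axial factor
#' \eqn{\cos(2\pi q_z \Delta z)} is a function of \emph{defocus}, not of
#' absolute sample depth, and multiplies the PSF rather than the sample.
#' Each recorded slice stack is therefore
#' \deqn{D_p = s \otimes h_0
#'   + m_1\,[s\,L_{1,p}] \otimes [h_0 \cos(2\pi q_z z)]
#'   + m_2\,[s\,L_{2,p}] \otimes h_0}
#' with \eqn{h_0} the widefield PSF and \eqn{L_{1,p}, L_{2,p}} the
#' lateral first/second-order pattern factors of phase step p.  This is
#' what gives the first-order bands their two axial side-lobe transfer
#' function \eqn{[O(k - q_z) + O(k + q_z)]/2} (see \code{\link{bandOTF}}).
#'
#' Noiseless images are scaled so their global maximum equals
#' \code{peakPhotons}, then Poisson photon noise and Gaussian read noise
#' are applied and the result is rounded to nonnegative integer counts
#' (camera DN), which also makes TIFF round trips exact.  Optional
#' per-image phase jitter emulates grating stepper error; the
#' reconstruction still assumes nominal phase steps, reproducing the
#' residual pattern peaks real instruments show.  All randomness is
#' seeded from \code{config@seed}.
#'
#' @param gt a \linkS4class{GroundTruth}.
#' @param config a \linkS4class{SimConfig}.
#' @param noise set FALSE for the noiseless (continuous-valued) forward
#'   model, e.g. for oracle tests.
#' @param phaseJitterSd per-image random phase-step error, rad (0 =
#'   ideal stepper).
#' @return list with \code{stack} (a \linkS4class{RawStack}),
#'   \code{params} (list of ground-truth \linkS4class{PatternParams}, one
#'   per angle) and \code{scale} (photons per unit phantom density).
#' @export
simulateRawStack <- function(gt, config, noise = TRUE, phaseJitterSd = 0) {
  g <- config@geometry
  dims <- dim(gt@volume)
  if (config@peakPhotons <= 0) stop("peakPhotons must be positive")
  psf <- computePSF(g, dims)
  Ov <- ftn(psf)
  kc <- lateralCutoff(g, "px")
  pMag <- config@patternFreqFraction * kc / 2
  if (2 * pMag > 0.5)
    stop("second-order pattern frequency beyond the grid Nyquist")
  qz <- axialPatternFreq(g, pMag)
  coszArr <- array(cos(2 * pi * qz * centeredCoords(dims[1L])), dims)
  O1v <- ftn(psf * coszArr)
  nA <- length(config@patternAngles)
  if (nA != g@nAngles)
    stop("pattern angle count does not match the geometry")
  nP <- g@nPhases
  jit <- 0
  if (phaseJitterSd > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(config@seed + 1L)
    jit <- stats::rnorm(nA * nP, sd = phaseJitterSd)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  jit <- matrix(jit, nA, nP)
  S0 <- ftn(gt@volume) * Ov
  gr <- grid3(centeredCoords(dims[1L]), centeredCoords(dims[2L]),
              centeredCoords(dims[3L]))
  imgs <- array(0, c(nA, nP, dims))
  for (a in seq_len(nA)) {
    alpha <- config@patternAngles[a]
    pvec <- pMag * c(cos(alpha), sin(alpha))       # (kx, ky)
    thBase <- 2 * pi * (pvec[1L] * gr$x + pvec[2L] * gr$y)
    for (p in seq_len(nP)) {
      phi <- config@phi0[a] + 2 * pi * (p - 1L) / nP + jit[a, p]
      th <- thBase + phi
      em <- Re(iftn(S0 +
        config@modulationM1 * ftn(gt@volume * cos(th)) * O1v +
        config@modulationM2 * ftn(gt@volume * cos(2 * th)) * Ov))
      imgs[a, p, , , ] <- pmax(em, 0)
    }
  }
  mx <- max(imgs)
  if (mx == 0) stop("phantom produced an all-zero acquisition")
  imgs <- imgs * (config@peakPhotons / mx)
  if (noise) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(config@seed)
    n <- length(imgs)
    imgs[] <- stats::rpois(n, lambda = imgs) +
      stats::rnorm(n, sd = config@readNoiseSd)
    imgs <- pmax(round(imgs), 0)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  params <- lapply(seq_len(nA), function(a) {
    alpha <- config@patternAngles[a]
    new("PatternParams",
        p = pMag * c(cos(alpha), sin(alpha)), qz = qz,
        phi0 = config@phi0[a] %% (2 * pi),
        m1 = config@modulationM1, m2 = config@modulationM2,
        source = "SECOND_ORDER", reliability = Inf,
        depthClipped = c(FALSE, FALSE))
  })
  stack <- new("RawStack", data = imgs, geometry = g,
               channelId = 1L, timeId = 1L)
  list(stack = stack, params = params, scale = config@peakPhotons / mx)
}

#' Simulated per-angle intensities of a polarized excitation series
#'
#' Malus-law forward model for dipole imaging: the phase-averaged
#' widefield intensity of angle \eqn{a} with excitation polarization
#' azimuth \eqn{\alpha_a} is
#' \eqn{I_a = g_a\,[dc + A\cos 2(\alpha_a - \theta)]}, where \eqn{g_a}
#' is an optional per-angle illumination factor (nonuniformity).
#'
#' @param dc,amplitude,theta matrices (or scalars) of mean intensity,
#'   modulation amplitude and dipole azimuth (rad).
#' @param alphas excitation polarization azimuths, rad.
#' @param illumFactors per-angle illumination gain (scalar or matrix each).
#' @return list of intensity matrices, one per angle.
#' @export
simulatePolarizedMeans <- function(dc, amplitude, theta, alphas,
                                   illumFactors = rep(1, length(alphas))) {
  lapply(seq_along(alphas), function(a) {
    illumFactors[[a]] * (dc + amplitude * cos(2 * (alphas[a] - theta)))
  })
}
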