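# band shifting and generalized Wiener combination

test_that("shiftBand with zero shift is the padded embedding", {
  set.seed(41)
  band <- sim3dr:::ftn(array(rnorm(4 * 16 * 16), c(4, 16, 16)))
  E <- sim3dr:::embedLateral(sim3dr:::zeroNyquist(band), 32, 32)
  expect_lt(max(Mod(shiftBand(band, c(0, 0)) - E)), 1e-10 * max(Mod(band)))
})

test_that("a peak at +p relocates to DC when shifted by -p", {
  n <- 32
  p <- c(0.17, 0.11)   # (kx, ky), off-grid
  gr <- sim3dr:::grid3(sim3dr:::centeredCoords(4), sim3dr:::centeredCoords(n),
                       sim3dr:::centeredCoords(n))
  carrier <- exp(2i * pi * (p[1] * gr$x + p[2] * gr$y))
  band <- sim3dr:::ftn(carrier)
  Bs <- shiftBand(band, -p)
  # peak of the shifted spectrum sits at DC to subpixel tolerance
  imax <- arrayInd(which.max(Mod(Bs)), dim(Bs))
  expect_equal(imax[2:3], c(33, 33))
  expect_gt(Mod(Bs[3, 33, 33]) / sqrt(sum(Mod(Bs)^2)), 0.95)
})

test_that("shift then inverse shift returns the original band", {
  set.seed(42)
  band <- sim3dr:::ftn(array(rnorm(4 * 16 * 16), c(4, 16, 16)))
  s <- c(0.123, -0.071)
  there <- shiftBand(band, s)
  back <- shiftBand(there, -s, embedded = TRUE)
  expect_lt(max(Mod(back - shiftBand(band, c(0, 0)))), 1e-9 * max(Mod(band)))
})

test_that("shifts beyond the padded Nyquist are refused", {
  band <- array(0 + 0i, c(2, 8, 8))
  expect_error(shiftBand(band, c(1.2, 0)), "Nyquist")
})

test_that("single-band combination equals the closed-form Wiener quotient", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(6, 32, 32), seed = 5)
  cfg <- simConfig(peakPhotons = 500, seed = 1)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(6, 32, 32, g)
  bs <- angleBands(sim$stack, 1, taperAlpha = 0)
  pp <- sim$params[[1]]
  fs <- filterSpec(wienerW = 1e-6, notchEnabled = FALSE,
                   apoCutoffLateral = Inf, apoCutoffAxial = Inf)
  asm <- wienerCombine(list(bs), list(pp), otf, fs, orders = 0L)
  # independent quotient: conj(O) B / (|O|^2 + w^2) on the padded grid
  O <- bandOTF(otf, 0L)
  B <- sim3dr:::embedLateral(sim3dr:::zeroNyquist(bands(bs)[["0"]]), 64, 64)
  oracle <- Conj(O) * B / (Mod(O)^2 + 1e-12)
  expect_lt(max(Mod(asm@values - oracle)), 1e-6 * max(Mod(oracle)))
})

test_that("modulation depths change the scale but not the support mask", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(6, 32, 32), seed = 5)
  cfg <- simConfig(peakPhotons = 500, seed = 1)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(6, 32, 32, g)
  bs <- angleBands(sim$stack, 1)
  mk <- function(m1, m2) new("PatternParams", p = sim$params[[1]]@p,
                             qz = sim$params[[1]]@qz, phi0 = 0, m1 = m1, m2 = m2,
                             source = "SECOND_ORDER", reliability = 10,
                             depthClipped = c(FALSE, FALSE))
  a1 <- wienerCombine(list(bs), list(mk(0.15, 0.15)), otf)
  a2 <- wienerCombine(list(bs), list(mk(1, 1)), otf)
  expect_identical(a1@effectiveSupport, a2@effectiveSupport)
})

test_that("reconstruction is deterministic, real, 2x laterally upsampled", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(6, 48, 48), seed = 5)
  cfg <- simConfig(peakPhotons = 500, seed = 1)
  sim <- simulateRawStack(gt, cfg)
  r1 <- suppressMessages(reconstructSIM(sim$stack))
  r2 <- suppressMessages(reconstructSIM(sim$stack))
  expect_identical(reconVolume(r1), reconVolume(r2))
  expect_identical(dim(reconVolume(r1)), c(6L, 96L, 96L))
  # conjugate-symmetric assembly: inverse transform is real
  expect_lt(provenance(r1)$imagRel, 1e-6)
  expect_true(all(is.finite(reconVolume(r1))))
  expect_identical(provenance(r1)$params[[1]]$source, "SECOND_ORDER")
})

test_that("total reconstructed intensity shows no runaway amplification", {
  # Filter 1 deliberately removes the DC pedestal, so the default pipeline
  # only has to stay bounded above; the notch-free path conserves energy
  # within a factor 2
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(6, 48, 48), seed = 5)
  fsPlain <- filterSpec(notchEnabled = FALSE)
  for (photons in c(50, 500)) {
    cfg <- simConfig(peakPhotons = photons, seed = 2)
    sim <- simulateRawStack(gt, cfg)
    wfTotal <- sum(widefieldVolume(sim$stack))
    rec <- suppressMessages(reconstructSIM(sim$stack))
    expect_lt(sum(reconVolume(rec)) / wfTotal, 2)
    recPlain <- suppressMessages(reconstructSIM(sim$stack, filters = fsPlain))
    ratio <- sum(reconVolume(recPlain)) / wfTotal
    expect_gt(ratio, 0.5)
    expect_lt(ratio, 2)
  }
})

test_that("zeroing the side bands reduces the pipeline to deconvolved widefield", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(6, 32, 32), seed = 5)
  cfg <- simConfig(peakPhotons = 500, seed = 1)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(6, 32, 32, g)
  bs <- angleBands(sim$stack, 1, taperAlpha = 0)
  pp <- sim$params[[1]]
  fs <- filterSpec(notchEnabled = FALSE, apoCutoffLateral = Inf,
                   apoCutoffAxial = Inf)
  asm <- wienerCombine(list(bs), list(pp), otf, fs, orders = 0L)
  O <- bandOTF(otf, 0L)
  B <- sim3dr:::embedLateral(sim3dr:::zeroNyquist(bands(bs)[["0"]]), 64, 64)
  oracle <- Conj(O) * B / (Mod(O)^2 + 0.05^2)
  expect_lt(max(Mod(asm@values - oracle)), 1e-9 * max(Mod(oracle)))
})

test_that("degenerate inputs are rejected with stage-appropriate errors", {
  g <- defaultGeom()
  otf <- cachedOTF(6, 32, 32, g)
  expect_error(wienerCombine(list(), list(), otf), "empty band list")
  gt <- makePhantom("filaments", c(6, 32, 32), seed = 5)
  sim <- simulateRawStack(gt, simConfig(peakPhotons = 500, seed = 1), noise = FALSE)
  bs <- angleBands(sim$stack, 1)
  bs@bands[["1"]][1] <- NaN
  expect_error(wienerCombine(list(bs), sim$params[1], otf), "NaN")
  # a stack with a non-finite pixel aborts at validation with the stage named
  dat <- rawData(sim$stack); dat[1, 1, 1, 1, 1] <- NA
  bad <- new("RawStack", data = dat, geometry = g, channelId = 1L, timeId = 1L)
  expect_error(suppressMessages(reconstructSIM(bad)), "stage 'validate'")
})
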