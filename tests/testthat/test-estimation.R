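# cross-correlation pattern estimation

flatOTF <- function(nz, ny, nx, g = defaultGeom()) {
  psf <- array(0, c(nz, ny, nx))
  psf[floor(nz / 2) + 1, floor(ny / 2) + 1, floor(nx / 2) + 1] <- 1
  psfToOTF(psf, g)
}

test_that("a constructed integer shift lands the correlation peak on that bin", {
  set.seed(21)
  n <- 64
  otf <- flatOTF(4, n, n)
  base <- array(complex(real = rnorm(4 * n * n), imaginary = rnorm(4 * n * n)),
                c(4, n, n))
  i0 <- sim3dr:::iftn(base)
  gr <- sim3dr:::grid3(sim3dr:::centeredCoords(4), sim3dr:::centeredCoords(n),
                       sim3dr:::centeredCoords(n))
  im <- i0 * exp(2i * pi * (5 * gr$y + 3 * gr$x) / n)
  corr <- crossCorrelationMap(base, sim3dr:::ftn(im), otf)
  pk <- locatePeakSubpixel(corr)
  expect_equal(unname(pk$freq["ky"]), 5 / n, tolerance = 1e-6)
  expect_equal(unname(pk$freq["kx"]), 3 / n, tolerance = 1e-6)
})

test_that("self-correlation peaks at zero shift with a real-positive value", {
  set.seed(22)
  n <- 32
  otf <- flatOTF(4, n, n)
  base <- sim3dr:::ftn(array(runif(4 * n * n), c(4, n, n)))
  corr <- crossCorrelationMap(base, base, otf)
  pk <- locatePeakSubpixel(corr)
  expect_lt(sqrt(sum(pk$freq^2)), 1e-6)
  expect_gt(Re(pk$value), 0)
  expect_lt(abs(Arg(pk$value)), 1e-6)
})

test_that("uncorrelated spectra give peak contrast near 1", {
  set.seed(23)
  n <- 64
  otf <- flatOTF(2, n, n)
  contrasts <- replicate(20, {
    a <- array(complex(real = rnorm(2 * n * n), imaginary = rnorm(2 * n * n)),
               c(2, n, n))
    b <- array(complex(real = rnorm(2 * n * n), imaginary = rnorm(2 * n * n)),
               c(2, n, n))
    locatePeakSubpixel(crossCorrelationMap(a, b, otf))$contrast
  })
  # the argmax of a featureless surface scores ~1.3 against the
  # near-extreme annulus level -- far below the reliability thresholds
  expect_lt(median(contrasts), 1.5)
  expect_true(all(contrasts < 2.5))
})

test_that("a pure cosine frequency is recovered to 5e-4 cycles/px on a 256 grid", {
  n <- 256
  f0 <- 0.1837
  xc <- sim3dr:::centeredCoords(n)
  img <- outer(rep(1, n), cos(2 * pi * f0 * xc))
  q <- array(complex(real = img), c(1, n, n))   # product field with the carrier
  corr <- sim3dr:::.corrFromProduct(q)
  pk <- locatePeakSubpixel(corr, upsample = 64L)
  expect_lt(abs(sqrt(sum(pk$freq^2)) - f0), 5e-4)
})

test_that("twin equal peaks break ties to the lexicographically smaller frequency", {
  n <- 32
  q <- array(0 + 0i, c(1, n, n))
  # two exact delta peaks at +/- 5 bins in ky
  q[1, , ] <- outer(cos(2 * pi * 5 * sim3dr:::centeredCoords(n) / n), rep(1, n))
  corr <- sim3dr:::.corrFromProduct(q)
  pk <- locatePeakSubpixel(corr)
  # the mirror peak's sidelobes bias the zoomed refinement slightly, so
  # assert the sign choice and half-bin accuracy
  expect_lt(abs(unname(pk$freq["ky"]) + 5 / n), 0.5 / n)
  expect_lt(abs(unname(pk$freq["kx"])), 0.5 / n)
})

test_that("a flat surface reports contrast 1 (unreliable)", {
  q <- array(0 + 0i, c(1, 32, 32))
  corr <- sim3dr:::.corrFromProduct(q)
  pk <- locatePeakSubpixel(corr)
  expect_equal(pk$contrast, 1)
})

test_that("noiseless simulated stacks yield second-order estimates at spec accuracy", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  cfg <- simConfig(peakPhotons = 500, seed = 1, phi0 = c(0.7, 1.9, 4.1))
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(8, 64, 64, g)
  for (a in 1:3) {
    pp <- estimateQuiet(angleBands(sim$stack, a), otf)
    tr <- sim$params[[a]]
    expect_identical(pp@source, "SECOND_ORDER")
    expect_lt(sqrt(sum((pp@p - tr@p)^2)), 0.002)
    expect_lt(angDiff(pp@phi0, tr@phi0), 0.05)
    expect_equal(pp@qz, tr@qz, tolerance = 0.01)
  }
})

test_that("initial phase is recovered across a full sweep (noiseless)", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  otf <- cachedOTF(8, 64, 64, g)
  for (phi in 2 * pi * (0:4) / 5) {
    cfg <- simConfig(peakPhotons = 500, seed = 1, phi0 = rep(phi, 3))
    sim <- simulateRawStack(gt, cfg, noise = FALSE)
    pp <- estimateQuiet(angleBands(sim$stack, 1), otf)
    expect_lt(angDiff(pp@phi0, phi), 0.05)
  }
})

test_that("the three pattern azimuths are recovered to half a degree", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  cfg <- simConfig(peakPhotons = 500, seed = 1, phi0 = c(0.7, 1.9, 4.1))
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(8, 64, 64, g)
  az <- sapply(1:3, function(a) {
    pp <- estimateQuiet(angleBands(sim$stack, a), otf)
    atan2(pp@p[2], pp@p[1])
  })
  expect_lt(angDiff(az[2] - az[1], pi / 3, mod = pi), 0.5 * pi / 180)
  expect_lt(angDiff(az[3] - az[2], pi / 3, mod = pi), 0.5 * pi / 180)
})

test_that("zero modulation depth makes estimation fail with an angle-naming error", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  cfg <- simConfig(peakPhotons = 500, seed = 1, modulationM1 = 0, modulationM2 = 0)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(8, 64, 64, g)
  expect_error(estimateQuiet(angleBands(sim$stack, 1), otf),
               "estimation failed for angle 1")
})

test_that("forceFallback and freqOverride control the estimation path", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  cfg <- simConfig(peakPhotons = 500, seed = 1)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(8, 64, 64, g)
  bs <- angleBands(sim$stack, 1)
  pp <- estimateQuiet(bs, otf, forceFallback = TRUE)
  expect_identical(pp@source, "FIRST_ORDER_FALLBACK")
  expect_lt(sqrt(sum((pp@p - sim$params[[1]]@p)^2)), 0.002)
  ppo <- estimateQuiet(bs, otf, freqOverride = sim$params[[1]]@p)
  expect_equal(unname(ppo@p), unname(sim$params[[1]]@p))
})

test_that("frequency error does not improve as photons decrease (median over seeds)", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  otf <- cachedOTF(8, 64, 64, g)
  # compare across the 10x range where photon noise, not the small
  # scene-induced bias, limits the estimate
  err <- function(photons, seed) {
    cfg <- simConfig(peakPhotons = photons, seed = seed)
    sim <- simulateRawStack(gt, cfg)
    pp <- tryCatch(estimateQuiet(angleBands(sim$stack, 2), otf, upsample = 64L),
                   error = function(e) NULL)
    if (is.null(pp)) return(Inf)
    sqrt(sum((pp@p - sim$params[[2]]@p)^2))
  }
  seeds <- 1:10
  eHigh <- median(sapply(seeds, function(s) err(50, s)))
  eLow <- median(sapply(seeds, function(s) err(5, s)))
  expect_gte(eLow, eHigh)
})

test_that("modulation depths are clipped into [mMin, 1] with the event recorded", {
  g <- defaultGeom()
  gt <- makePhantom("filaments", c(8, 64, 64), seed = 3)
  cfg <- simConfig(peakPhotons = 500, seed = 1, modulationM2 = 0.02)
  sim <- simulateRawStack(gt, cfg, noise = FALSE)
  otf <- cachedOTF(8, 64, 64, g)
  bs <- angleBands(sim$stack, 1)
  expect_message(
    estimatePattern(bs, otf, freqOverride = sim$params[[1]]@p),
    "clipped")
  pp <- estimateQuiet(bs, otf, freqOverride = sim$params[[1]]@p)
  expect_gte(pp@m2, 0.15)
  expect_true(pp@depthClipped[2])
})
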