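# raw-stack readers for the three on-disk layouts, validation, volume I/O

# independent oracle: enumerate every page per the layout definitions and
# write the file directly with the tiff package
writeLayoutOracle <- function(path, layout, nA, nP, nZ, ny, nx, val) {
  if (layout == "NSIM") {
    pages <- lapply(seq_len(nZ), function(z) {
      pg <- matrix(0, nA * ny, nP * nx)
      for (a in seq_len(nA)) for (p in seq_len(nP))
        pg[(a - 1) * ny + seq_len(ny), (p - 1) * nx + seq_len(nx)] <- val(a, p, z)
      pg
    })
  } else {
    pages <- vector("list", nA * nP * nZ)
    for (a in seq_len(nA)) for (p in seq_len(nP)) for (z in seq_len(nZ)) {
      idx <- switch(layout,
        OMX = (p - 1) + nP * ((z - 1) + nZ * (a - 1)),
        HOMEBUILT = (p - 1) + nP * ((a - 1) + nA * (z - 1))) + 1
      pages[[idx]] <- matrix(val(a, p, z), ny, nx)
    }
  }
  tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                  bits.per.sample = 16L, compression = "none")
}

test_that("loader recovers the (angle, phase, z) encoding in all three layouts", {
  enc <- function(a, p, z) 100 * a + 10 * p + z
  for (layout in c("OMX", "HOMEBUILT", "NSIM")) {
    g <- defaultGeom(layout = layout)
    f <- withr::local_tempfile(fileext = ".tif")
    writeLayoutOracle(f, layout, 3, 5, 3, 8, 6, enc)
    st <- loadRawStack(f, g)
    expect_identical(dim(rawData(st)), c(3L, 5L, 3L, 8L, 6L))
    for (a in 1:3) for (p in 1:5) for (z in 1:3)
      expect_true(all(rawData(st)[a, p, z, , ] == enc(a, p, z)),
                  info = sprintf("%s a%d p%d z%d", layout, a, p, z))
  }
})

test_that("a 45-page OMX file yields a (3, 5, 3, Y, X) stack", {
  g <- defaultGeom()
  f <- withr::local_tempfile(fileext = ".tif")
  writeLayoutOracle(f, "OMX", 3, 5, 3, 16, 16, function(a, p, z) a + p + z)
  expect_identical(dim(rawData(loadRawStack(f, g))), c(3L, 5L, 3L, 16L, 16L))
})

test_that("write/load round trip is bit-exact in every layout", {
  set.seed(7)
  dat <- array(as.double(sample(0:4095, 3 * 5 * 2 * 8 * 8, TRUE)), c(3, 5, 2, 8, 8))
  for (layout in c("OMX", "HOMEBUILT", "NSIM")) {
    g <- defaultGeom(layout = layout)
    st <- new("RawStack", data = dat, geometry = g, channelId = 1L, timeId = 1L)
    f <- withr::local_tempfile(fileext = ".tif")
    writeRawStack(st, f, layout)
    expect_identical(rawData(loadRawStack(f, g)), dat, label = layout)
  }
})

test_that("non-integer stacks round-trip exactly at the 32-bit quantization", {
  set.seed(8)
  dat <- array(runif(3 * 5 * 2 * 8 * 8) * 900, c(3, 5, 2, 8, 8))
  g <- defaultGeom()
  st <- new("RawStack", data = dat, geometry = g, channelId = 1L, timeId = 1L)
  f <- withr::local_tempfile(fileext = ".tif")
  writeRawStack(st, f)
  once <- rawData(loadRawStack(f, g))
  expect_lt(max(abs(once - dat)), 2048 / 2^31)  # quantization on the 2048 scale
  st2 <- new("RawStack", data = once, geometry = g, channelId = 1L, timeId = 1L)
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeRawStack(st2, f2)
  expect_identical(rawData(loadRawStack(f2, g)), once)  # stable fixed point
})

test_that("page-count and montage mismatches raise layout errors naming the counts", {
  g <- defaultGeom()
  f <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(lapply(1:14, function(i) matrix(0.1, 4, 4)), f,
                  bits.per.sample = 16L)
  expect_error(loadRawStack(f, g), "14 pages not divisible by 3 angles x 5 phases")
  gN <- defaultGeom(layout = "NSIM")
  fN <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.1, 10, 14), fN, bits.per.sample = 16L)  # 14 %% 5 != 0
  expect_error(loadRawStack(fN, gN), "tiling error")
})

test_that("native container formats are rejected with export advice", {
  expect_error(loadRawStack("acq.dv", defaultGeom()), "export the data")
  expect_error(loadRawStack("acq.nd2", defaultGeom()), "TIFF")
})

test_that("camera offset is subtracted and clamped at zero", {
  g <- defaultGeom()
  st <- new("RawStack", data = array(50, c(3, 5, 1, 4, 4)), geometry = g,
            channelId = 1L, timeId = 1L)
  f <- withr::local_tempfile(fileext = ".tif")
  writeRawStack(st, f)
  expect_true(all(rawData(loadRawStack(f, g, cameraOffset = 60)) == 0))
  expect_true(all(rawData(loadRawStack(f, g, cameraOffset = 20)) == 30))
})

test_that("validateStack reports the six-layer warning exactly at the boundary", {
  g <- defaultGeom()
  mk <- function(nz) new("RawStack", data = array(1, c(3, 5, nz, 4, 4)),
                         geometry = g, channelId = 1L, timeId = 1L)
  expect_length(validateStack(mk(6))$warnings, 0)
  expect_match(validateStack(mk(5))$warnings, "fewer than 6 z-layers")
})

test_that("validateStack locates non-finite pixels and flags saturation", {
  g <- defaultGeom()
  dat <- array(1, c(3, 5, 2, 4, 4))
  dat[2, 3, 1, 2, 2] <- NaN
  st <- new("RawStack", data = dat, geometry = g, channelId = 1L, timeId = 1L)
  rep_ <- validateStack(st)
  expect_match(rep_$errors, "angle 2, phase 3, z 1")
  dat2 <- array(1, c(3, 5, 6, 4, 4)); dat2[1, 1, 1, 1, 1] <- 70000
  st2 <- new("RawStack", data = dat2, geometry = g, channelId = 1L, timeId = 1L)
  expect_match(validateStack(st2)$warnings, "saturated")
})

test_that("volume TIFF output round-trips and embeds the halved pixel size", {
  set.seed(9)
  g <- defaultGeom()
  vol <- array(runif(4 * 8 * 8) * 1e4, c(4, 8, 8))
  rec <- new("Reconstruction", volume = vol, geometry = g,
             provenance = list(inputDim = c(4L, 4L, 4L)))
  f <- withr::local_tempfile(fileext = ".tif")
  writeVolume(rec, f)
  # one page per z-slice
  expect_length(tiff::readTIFF(f, all = TRUE), 4)
  v1 <- readVolume(f)
  expect_lt(max(abs(v1 - vol)), 32768 / 2^31)
  # second round trip is bit-exact (quantized values are write-stable)
  f2 <- withr::local_tempfile(fileext = ".tif")
  writeVolume(array(v1, dim(v1)), f2, geometry = g)
  expect_identical(array(readVolume(f2), dim(v1)), array(v1, dim(v1)))
  # metadata read back with an independent JSON reader
  meta <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(meta$dxy_nm, g@dxy / 2)
  expect_equal(meta$dz_nm, g@dz)
})
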