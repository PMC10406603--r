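# shared fixtures, built in code

defaultGeom <- function(...) acquisitionGeometry(...)

# memoised OTFs for common grid sizes (helpers are re-sourced per file,
# so the cache lives for one test file)
.otfCache <- new.env(parent = emptyenv())
cachedOTF <- function(nz, ny, nx, geom = defaultGeom()) {
  key <- paste(nz, ny, nx, sep = "x")
  if (is.null(.otfCache[[key]]))
    .otfCache[[key]] <- psfToOTF(computePSF(geom, c(nz, ny, nx)), geom)
  .otfCache[[key]]
}

nominalPhases <- function(n = 5L) 2 * pi * (seq_len(n) - 1L) / n

# separate one angle of a raw stack
angleBands <- function(stack, a, taperAlpha = 0.1) {
  d <- dim(rawData(stack))
  separateBands(array(rawData(stack)[a, , , , ], d[2:5]),
                nominalPhases(d[2L]), taperAlpha,
                geometry(stack), a)
}

estimateQuiet <- function(...) suppressMessages(estimatePattern(...))

# smallest wrapped difference between two angles (rad), modulo `mod`
angDiff <- function(a, b, mod = 2 * pi) {
  d <- (a - b) %% mod
  pmin(d, mod - d)
}
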