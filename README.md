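# sim3dr — multilayer 3D structured illumination microscopy reconstruction

Three-dimensional structured illumination microscopy (3D-SIM) doubles
the resolution of a fluorescence microscope in x, y *and* z by
illuminating the sample with a three-beam interference pattern. Each of
the 15 raw images per z-plane (3 pattern angles × 5 phase steps) mixes
five frequency bands of the object; separating, shifting and recombining
them restores frequencies up to twice the diffraction limit and fills
the "missing cone" of the widefield optical transfer function that
destroys optical sectioning. `sim3dr` is for microscopists and methods
developers who want an open, fully testable reconstruction path for
multilayer 3D-SIM stacks — including the low-signal regimes where naive
parameter estimation and filtering break down — plus fluorescent
dipole-orientation mapping from the angle-resolved data.

## What it does

* **Band separation** — per angle, the five phase-stepped volumes are
  unmixed with the pseudo-inverse of the phase matrix
  `M[p, m] = exp(i m φ_p)`, `m = −2…2`.
* **Parameter estimation** — pattern frequency, phase and modulation
  depth by cross-correlation between bands, with a reliability
  criterion on the second-order peak contrast (threshold 4) and an
  automatic fallback to the first-order peak, which survives far lower
  SNR. The axial pattern frequency follows from the beam geometry:
  `q_z = (n − sqrt(n² − |p|² λ_exc²))/λ_exc`.
* **Missing-cone filling** — first-order bands carry the two-lobe
  transfer function `[O(k−q_z) + O(k+q_z)]/2` of scanned three-beam
  acquisition; after the lateral shift their support covers the axial
  axis at ±q_z.
* **Generalized Wiener combination** with a two-step spectral filter:
  a Gaussian notch (Filter 1) that withdraws each band's vote at DC and
  the pattern frequencies, suppressing residual stripe peaks, and a
  smooth apodization (Filter 2) over the extended support:

  `S(k) = Σ d_m conj(O_notch) B_shifted / (Σ d_m² |O|² + w²) · Apo(k)`
* **Dipole orientation** (`pOpen`-style) — per-pixel cos 2θ fit over the
  three polarized excitation azimuths, with illumination-nonuniformity
  calibration from bead fields (`calib1 = ang2/ang1`,
  `calib2 = ang3/ang1`).
* **Metrics** — `MAE = (1/m) Σ|y − y′|` and
  `SNR(dB) = 10 log10[(mean(signal) − mean(noise))/sd(noise)]`,
  translation registration, FWHM measurement.
* **Forward simulator** — three-beam pattern, scalar pupil-propagation
  PSF, Poisson + read noise, phantoms (beads, filaments, axial sheet,
  uniform), so every stage is verifiable without microscope data.
* **Raw TIFF I/O** in the three common dimension orderings: OMX (phase,
  depth, channel, time, angle), N-SIM (angle×phase montage per plane)
  and home-built (phase, angle, depth, channel, time).

## Worked example

```r
library(sim3dr)

# simulate a 3-angle, 5-phase acquisition of a filament network
gt  <- makePhantom("filaments", c(8, 128, 128), seed = 3)
cfg <- simConfig(peakPhotons = 500, seed = 1, phi0 = c(0.7, 1.9, 4.1))
sim <- simulateRawStack(gt, cfg)

rec <- reconstructSIM(sim$stack)
rec
#> Reconstruction [z 8, y 256, x 256], pixel 40 x 125 nm
#>   negative values clipped: 68.5% of voxels

# estimated pattern parameters of angle 1 (truth: |p| = 0.1707, phi0 = 0.7)
str(provenance(rec)$params[[1]])
#> List of 7
#>  $ p          : num [1:2] 0.171 0
#>  $ qz         : num 0.106
#>  $ phi0       : num 0.701
#>  $ m1         : num 0.846
#>  $ m2         : num 0.15
#>  $ source     : chr "SECOND_ORDER"
#>  $ reliability: num 6.59

writeVolume(rec, "recon.tif")   # 32-bit TIFF + JSON sidecar (40 nm pixels)
```

The recovered frequency is accurate to ~1e-4 cycles/px and the initial
phase to ~0.003 rad; at 5 peak photons the same call switches every
angle to `FIRST_ORDER_FALLBACK` and still recovers the frequency to
better than 0.001 cycles/px. A command-line interface wrapping the same
functions is installed as `exec/sim3dr` with subcommands `reconstruct`,
`simulate`, `orientation` and `metrics`.

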