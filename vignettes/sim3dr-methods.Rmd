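---
title: "Multilayer 3D-SIM reconstruction: model, parameters and design choices"
author: "sim3dr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer 3D-SIM reconstruction: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sim3dr)
```

# The imaging model

Three-beam structured illumination microscopy (3D-SIM) illuminates the
sample with the interference pattern of an axial center beam and two
symmetric side beams produced by grating diffraction. After normalising
the pattern to unit mean, the intensity of phase step $p$ at pattern
azimuth $\alpha$ is

$$
I(\mathbf r) \;=\; 1 \;+\; m_1 \cos(2\pi q_z z)\,\cos\theta
\;+\; m_2 \cos 2\theta,
\qquad
\theta = 2\pi\,\mathbf p\cdot\mathbf r_{xy} + \phi_0 + \tfrac{2\pi p}{5},
$$

where $\mathbf p$ is the lateral first-order frequency (the second order
sits at $2\mathbf p$), $m_1, m_2$ are the modulation depths, and the
axial beat frequency is fixed by the beam geometry:

$$
q_z = \frac{n - \sqrt{\,n^2 - |\mathbf p|^2 \lambda_{exc}^2\,}}{\lambda_{exc}} .
$$

Each raw image therefore mixes five object bands (orders
$m = -2 \dots 2$), which is why five phase steps per angle are the
minimum and a conforming acquisition holds $3 \times 5 = 15$ raw images
per z-plane.

## Scanned acquisition and the two-lobe band transfer function

A point that decides the whole algebra: the interference pattern is
locked to the objective's focal plane, and the z-stack is acquired by
stepping the sample through it. The axial factor $\cos(2\pi q_z z)$ is
consequently a function of *defocus*, not of absolute sample depth, so it
multiplies the imaging kernel rather than the sample. Writing $h_0$ for
the widefield PSF, the recorded stack of phase step $p$ is

$$
D_p = s \otimes h_0
  + m_1\, [\,s\,L_{1,p}\,] \otimes \left[h_0 \cos(2\pi q_z z)\right]
  + m_2\, [\,s\,L_{2,p}\,] \otimes h_0 ,
$$

with $L_{1,p}, L_{2,p}$ the lateral first/second-order pattern factors.
In frequency space the first-order bands carry a single object copy with
the *two-lobe* transfer function

$$
O_1(\mathbf k) = \tfrac12\left[O(\mathbf k - q_z \hat z) + O(\mathbf k + q_z \hat z)\right],
$$

whose support reaches the axial frequency axis at $\pm q_z$ — inside the
widefield missing cone. (Under the naive alternative, a static 3-D
pattern multiplying the whole volume, a fluorophore sitting at a null of
the axial envelope would carry no first-order information at all; we
verified numerically that that model produces bimodal axial resolution
across beads and is inconsistent with the two-lobe transfer function.
The simulator therefore implements the scanned model, which makes the
forward model, the band OTFs and the Wiener combination mutually
consistent.)

The optical model itself is scalar pupil propagation: per defocus $z$
the coherent field is the inverse transform of
$P(\mathbf k)\exp\!\big(i2\pi z\sqrt{(n/\lambda_{em})^2-|\mathbf k|^2}\big)$
over the pupil disc, and the PSF is its squared modulus. For this model
the lateral energy per plane is exactly constant in $z$, so the
widefield OTF vanishes identically on the axial axis away from DC — the
missing cone is exact, not approximate, which the test suite asserts at
`1e-3`.

# The reconstruction pipeline

1. **Validation and normalisation.** Frame multiplicity and finiteness
   are errors; fewer than six z-layers or saturated pixels are warnings
   (reconstruction proceeds). Each angle's global mean is scaled to the
   first angle's to keep bleaching/illumination drift out of the bands.
2. **Taper and separation.** A lateral Tukey window (fraction 0.1)
   suppresses spectral leakage that would masquerade as stripe
   artifacts; each phase volume is 3-D transformed as a whole (the axial
   band structure requires it) and the five bands are unmixed with the
   pseudo-inverse of $M[p,m]=e^{im\phi_p}$.
3. **Parameter estimation.** See below.
4. **Shift and combine.** Order-$m$ bands are translated by
   $-m\hat{\mathbf p}$ on the 2× laterally padded grid by exact
   subpixel modulation, and merged by the generalized Wiener formula
   with the apodization applied once at the end.
5. **Inverse transform,** optional clipping of negative intensities
   (recorded in the provenance), output at half the lateral pixel size.

## Cross-correlation parameter estimation

The correlation of band $m$ against band 0 over all lateral shifts is
computed as the lateral transform of the z-summed pointwise product of
their OTF-weighted real-space fields; it peaks at $m\mathbf p$. Design
choices that matter in practice:

* **Both spectra are flattened** by $|O|/(|O|^2+0.15^2)$ — a Wiener-like
  weighting of the common support that sharpens the carrier peak without
  amplifying frequencies the system never measured.
* **Search normalisation.** The correlation magnitude is divided by its
  radially smoothed median background before the argmax. For compact
  scenes (bead fields) the object's broad self-correlation envelope
  around DC otherwise outvotes the sharp carrier peak riding on it; the
  normalisation is scale-free and does not move well-separated peaks.
* **Reliability contrast** is the peak magnitude over the
  99.5th-percentile magnitude in a surrounding annulus (radii 5–15
  bins). Normalising by a near-extreme rather than the median keeps the
  statistic calibrated: the argmax of a featureless surface is itself an
  extreme value, and would score ≈4 against the median — exactly at the
  acceptance threshold — whereas here it scores ≈1. The second-order
  peak is accepted when its contrast reaches $R_{min}=4$; otherwise the
  first-order peak (which survives far lower SNR, being both stronger
  and better transferred) supplies the frequency, doubled for the
  second-order shift and flagged `FIRST_ORDER_FALLBACK`. Below contrast
  2 on the first order, estimation fails with an error naming the angle.
* **Phase.** $\phi_0$ is always read from the first-order correlation at
  the refined frequency — the second-order correlation carries
  $2\phi_0$, ambiguous by $\pi$ when halved.
* **Modulation depths** are correlation-to-autocorrelation ratios
  divided by the OTF passband overlap factor at the estimated shift
  (computable from the OTF; the raw ratio absorbs it), so they land on
  the illumination-coefficient scale. They are clipped to
  $[0.15, 1]$ before use as Wiener weights — the floor avoids noise
  amplification by near-zero division — and clip events are logged.
* $q_z$ is **computed from the geometry**, never estimated: three-beam
  interference fixes it, and estimating it from noisy data is strictly
  less stable.
* **Subpixel refinement** evaluates a zoomed DFT of the product field in
  a ±1.5-bin neighbourhood at 1/32 bin steps; exact ties break to the
  lexicographically smaller $(k_y, k_x)$.

## Generalized Wiener combination and the two-step filter

$$
S(\mathbf k) =
\frac{\sum_{a,m} d_m\, \overline{O^{notch}_{a,m}}\, \tilde B_{a,m}}
     {\sum_{a,m} d_m^2 |O_{a,m}|^2 + w^2}\; A(\mathbf k),
\qquad d_0 = 1,\; d_{\pm1} = \tfrac{m_1}{2},\; d_{\pm2} = \tfrac{m_2}{2}.
$$

**Filter 1** is a product of inverted Gaussians (depth 0.98 at DC, 0.9
at $\pm\mathbf p, \pm2\mathbf p$; width two frequency samples of the
input image) applied to the *numerator* transfer functions only. This
placement is deliberate: a band whose vote is withdrawn near the pattern
frequencies cannot deposit its residual carrier there, so the peaks that
phase-step errors leave behind are suppressed about tenfold at their
centers. Notching the denominator as well — which a symmetric reading of
the formula would suggest — cancels the attenuation again (the quotient
renormalises) and with a small $w$ actually *amplifies* the peaks ~16×;
we verified this numerically and kept the numerator-only form, which is
the behaviour the two-step filter exists to produce.

**Filter 2** is the generalized-ellipsoid apodization
$A = (1-d)^{\gamma}$, $d^2 = (|k_{xy}|/c_{xy})^2 + (k_z/c_z)^2$, with
$\gamma = 0.9$ and cutoffs at the extended support
($k_c + |2\mathbf p|$ laterally, $k_{c,z} + q_z$ axially, clamped to the
grid Nyquist). It is monotone along every ray from DC, 1 at DC, 0
outside — shaping the effective PSF and preventing ringing at the hard
support edge.

The Wiener constant $w$ (default 0.05 on the OTF-normalised scale) is
the primary user knob: larger values trade resolution for noise
suppression.

## Numerical choices

* All spectra are DC-centered with the zero-frequency sample at index
  $\lfloor n/2\rfloor + 1$; real-space coordinates are centered the same
  way, so pattern phases are referenced to the volume center.
* Band shifting is exact subpixel translation (real-space modulation by
  a complex exponential), not bin rolling.
* The unpaired $-$Nyquist planes of even-length axes are zeroed before
  shifting: they have no $+$Nyquist partner, so content there would
  break conjugate symmetry of the assembled spectrum; for band-limited
  data they sit beyond the OTF support and carry nothing. The inverse
  transform of the assembled spectrum is then real to better than
  $10^{-6}$ relative, which the suite asserts.
* Lateral padding is 2×; the axial sampling is unchanged because
  $q_z + k_{c,z}$ stays below the axial Nyquist for the supported
  geometries (checked at combine time).
* The pipeline contains no randomness: reconstructions are bit-identical
  across runs.

# The forward simulator

The simulator exists so that every stage is verifiable without external
data. It emulates: the three-beam pattern of the scanned acquisition
(above), scalar-PSF blurring, Poisson photon noise plus Gaussian read
noise (default sd 1 photon), and rounding to nonnegative integer camera
counts — which also makes TIFF round trips exact. All randomness derives
from one seed.

Defaults are the study conditions used throughout the tests:

* OMX-like geometry: NA 1.4 oil (n 1.518), 488/525 nm, 80 nm lateral
  pixels, 125 nm z-steps, 3 angles at 0°/60°/120°, 5 phases.
* `patternFreqFraction = 0.8`: the *finest* illumination component at
  0.8 of the detection cutoff, $2|\mathbf p| = 0.8\,k_c$. (Reading the
  fraction as $|\mathbf p|/k_c$ would require a side beam beyond the
  excitation pupil — $q_z$ becomes imaginary — and would contradict the
  estimator's own search annulus; resolution measurements use the
  pupil-edge fraction $\lambda_{em}/\lambda_{exc} \approx 1.08$, the
  geometry of the real instruments, where the axial support truly
  doubles.)
* Beam amplitude ratio $E_0{:}E_\pm = 2+\sqrt2$, the smallest
  center:side ratio whose first-order depth does not exceed 1; it gives
  exactly $m_1 = 1$ and $m_2 = 1/(2R) \approx 0.146$.
* Optional per-image phase jitter (`phaseJitterSd`) emulates grating
  stepper error; with ideal phases the separation is exact and the
  assembled spectrum shows no residual pattern peaks at all, so the
  filter tests run at a realistic 0.15 rad jitter — the condition the
  notch exists for.

Phantoms: `beads` (isolated points with a minimum separation; a single
bead is centered), `filaments` (smooth random curves reflected at the
borders, a dense network like a labelled cytoskeleton), `sheet_z`
(axial-only modulation — invisible to widefield imaging because of the
missing cone), `uniform`, and an optional uniform `background` pedestal
emulating diffuse out-of-focus fluorescence.

What passing simulations do *not* show about real data: the scalar PSF
has no aberrations, depth dependence or vectorial high-NA effects; the
noise model has a single gain and no sample motion or bleaching; phase
errors are white. Estimation accuracy and filter behaviour on real
stacks will be somewhat worse than the simulated figures.

## Problem sizes used by the tests

Unit tests run on 32–64 px lateral grids with 4–8 planes; the
parameter-recovery and filter checks use 128×128×8; the bead-resolution
check uses 256×256×16 with a 60-bead field (a single bead gives a
textureless correlation surface — contrast ≈ 1 — so estimation
legitimately refuses it; medians over ~9 central beads also tame the
photon noise of individual profiles). These sizes were chosen as the
smallest grids on which each quantity is well resolved.

# Dipole-orientation mapping

With the excitation linearly polarized along each pattern azimuth, the
three per-angle widefield images (phase averages of the focal slice)
form a three-point Malus series at every pixel,
$I_a = dc + A\cos 2(\alpha_a - \theta)$, solved exactly through the
linear basis $\{1, \cos 2\alpha, \sin 2\alpha\}$; $\theta$ lands in
$[0, \pi)$ because a dipole is an axis, not an arrow. Pixels with
relative modulation below 0.05 (or mean intensity within 3 background
standard deviations of zero) carry no reliable angle and are masked.
Illumination nonuniformity is calibrated from dense bead fields by
normalised convolution (Gaussian-smoothed masked intensity over the
smoothed mask) and the ratio images
$\mathrm{calib}_1 = \mathrm{ang}_2/\mathrm{ang}_1$,
$\mathrm{calib}_2 = \mathrm{ang}_3/\mathrm{ang}_1$; corrected inputs are
$I_1,\; I_2/\mathrm{calib}_1,\; I_3/\mathrm{calib}_2$. The orientation
is estimated on the widefield per-angle images and overlaid on the
super-resolved volume for display — not a joint super-resolved
polarization inversion.

# Known limitations

* Measured-OTF import is plumbing only; the filters always use the
  scalar model.
* Per-step phase errors are not fitted (only the global $\phi_0$);
  drift and motion are not corrected.
* The estimated modulation depths are effective Wiener weights; their
  absolute scale is only as good as the scalar-OTF overlap model
  (systematically conservative by ~10–15% in simulation).
* `.dv`/`.nd2` containers are not parsed — export to TIFF first.
* The 32-bit TIFF output is quantized integer storage on a power-of-two
  scale (the available writer has no IEEE-float mode); the quantum,
  ~5e-10 of the intensity range, is recorded in a JSON sidecar along
  with the pixel sizes.
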