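---
title: "Deconstructing ultrasound image degradation: models, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconstructing ultrasound image degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(usdecon)
```

## The three mechanisms and why they separate

Medium-dependent degradation of an abdominal B-mode image decomposes into
three mechanisms with distinct physics and distinct signatures in the
point-spread function (PSF):

* **Phase/amplitude aberration** — distortion of the ballistic pulse by
  spatial variation of the *speed of sound*. It corrupts focusing and
  resolution, lives in the isochronous ("bow-tie") region of the PSF, and
  is independent of target brightness.
* **Multiple-reverberation clutter** — energy multiply reflected between
  proximal tissue layers. It arrives contemporaneously with deeper echoes
  but never interacts with the target, so its *image* impact depends on how
  bright the target is relative to the clutter floor. It fills the
  pre-isochronous region (and, via longer paths, the trailing region).
* **Trailing clutter** — forward-scattered energy that travels *with* the
  pulse, lengthens it, and is reflected by the target. Its amplitude is
  proportional to target reflectivity; its relative image impact is
  brightness independent. It lives behind the isochronous region.

Because speed of sound controls aberration while the *impedance* field
controls scattering, the two can be modified independently in a simulated
medium. That observation is the core of the package.

## The map-modulation algebra

For reference maps `c_ref(x, y)` and `rho_ref(x, y)` with impedance
`Z_ref = rho_ref * c_ref`:

* `isovelocity(maps, c0)` sets `c ≡ c0` and `rho_iv = Z_ref / c0`. The
  impedance field — and with it all scattering and reverberation — is
  preserved *exactly*, while aberration is removed. (Note the density must
  carry the impedance: dimensional consistency demands `Z_ref / c0`, and the
  identity `rho_iv * c0 = Z_ref` is enforced by construction and tested to
  relative error below 1e-12.)
* `isoimpedance(maps, Z0)` keeps `c = c_ref` and sets `rho_ii = Z0 / c_ref`,
  flattening the impedance everywhere: reverberation and backscatter are
  removed, aberration preserved.
* `modulate_maps(maps, modulation_params(gamma, zeta, c0, rho0, Z0))`
  interpolates continuously:

  ```
  c_m   = c0 + zeta * (c_ref - c0)
  Z_m   = rho_ref * c_m = Z0 + Z'
  rho_m = (Z0 + gamma * Z') / c_m
  ```

  `gamma = zeta = 1` is the identity; `gamma = zeta = 0` homogenizes to
  `(c0, rho0)`; `gamma = 0, zeta = 1` is pure isoimpedance; `zeta = 0`
  pins the speed at `c0` (isovelocity family); values above 1 exaggerate
  heterogeneity. The equilibrium constants default to the abdominal
  averages `c0 = 1570 m/s`, `rho0 = 1064 kg/m^3`, `Z0 = rho0 * c0 = 1.67
  MRayl`, and `Z0 = rho0 * c0` is required so the two zero limits agree.

A third, exact separation route needs no map surgery: simulate the full
medium twice, once with and once without the imaging target
(`clutter_pair()`), and subtract the records (`subtract_clutter()`). In a
linear solver the difference removes every path that does not touch the
target — multiple reverberation vanishes to the numerical noise floor —
while the ballistic echo, its aberration, and the trailing clutter that
the target reflected survive.

## The synthetic phantoms

`generate_layered_abdomen()` builds a labeled fat/muscle/connective wall
with smooth random interfaces over a homogeneous background. It emulates
the *statistics* that matter — speed contrast between layers (aberration),
impedance contrast (reverberation), interface roughness and lateral
correlation (the spatial spectrum of the effective phase screen) — and no
specific anatomy. Tissue properties (m/s, kg/m^3) default to water
1496/1000, fat 1450/950, muscle 1580/1050, connective 1613/1120,
background 1570/1064, all configurable via `tissue_properties()`.

`add_scatterers()` places single-pixel density perturbations at a mean
density per resolution cell (`resolution_cell_area()` = axial pulse length
x lateral FWHM beamwidth at focus). The calibrated speckle setting is 18
scatterers per resolution cell. Scatterers perturb *density only*, so they
add backscatter and reverberation but no aberration — this keeps the three
mechanisms separable by construction. Each scatterer multiplies the local
density by `1 + contrast * u`, `u ~ U(-1, 1)`; the anechoic-lesion
contrast-to-noise ratio was verified to be insensitive to the contrast
value over 0.05–0.3, so its default (0.05) is not a calibrated quantity.
`add_lesions()` restores all scatterer pixels strictly inside a disc —
lesions are exactly anechoic. `add_point_target()` inserts a density pixel
whose impedance realizes a requested reflectivity
`r = |Z_b - Z_t| / (Z_b + Z_t)`, i.e. `Z_t = Z_b (1 + r) / (1 - r)`.

Everything random is bit-reproducible for a fixed seed; generator state is
restored afterwards.

What the phantoms do **not** emulate: real segmented anatomy, attenuation
and nonlinearity (the solver is linear and lossless), elastic shear waves,
3D geometry, and out-of-plane scattering. Tests that pass on these
phantoms demonstrate the separation algebra and the metric machinery, not
clinical image quality.

## The desk-scale solver

`simulate_transmit()` integrates the first-order pressure–velocity system
on a staggered grid (leapfrog in time), with heterogeneous density
averaged onto cell faces. Numerical choices:

* **Grid**: 12 points per wavelength at `f0` in the slowest medium
  (enforced minimum 10); CFL number 0.5 (2D stability bound ~0.707).
* **Precision**: field arrays are single precision — the stencil is
  memory-bandwidth bound and the float rounding floor (~ -140 dB) sits far
  below every quantity of interest; matched simulation pairs cancel
  exactly because both runs execute identical arithmetic.
* **Boundaries**: an exponentially tapered sponge (default 40 px) with a
  tested normal-incidence reflection at least 40 dB down.
* **Sources**: each curved-array element spans one pitch of the arc,
  rasterized to grid pixels; transmit injects a delayed, apodized
  2-cycle Gaussian-windowed sinusoid as a soft pressure source; receive
  records the mean pressure over the element footprint.
* **RF sampling**: the solver-rate record is anti-alias filtered with a
  *zero-phase* (forward–backward) FIR before decimation to about
  `1/(12 f0)`. Zero phase matters: a causal anti-alias filter would add a
  resolution-dependent group delay to every arrival-time metric.
* **Known bias**: a second-order scheme at 12 points per wavelength
  carries ~0.5% group-velocity dispersion for a 50%-bandwidth pulse. All
  package metrics are *differential* (aberrated minus reference, full
  minus clutter), so the common-mode bias cancels; the refinement test
  verifies arrival-time convergence on a geometry-exact configuration.

Two canonical study profiles (`study_profile()`) fix the conditions of the
quantitative experiments: a 64-element, 0.4 mm-pitch, 40 mm-radius convex
array; 1.2 MHz for PSF/separation studies and 1.0 MHz for the deeper
sector-scan lesion study. These are scaled-down analogs of a clinical
abdominal probe (0.508 mm pitch, 3.7 MHz): every depth-like quantity of
the lesion experiment is scaled by 0.6 (lesion depths 24/36/48 mm for the
clinical 40/60/80 mm; the transmit focus at the deepest lesion), the 5 mm
lesion radius is kept, and the 0.6 factor is the smallest scale at which
adjacent 5 mm lesions remain disjoint. Sixty-four scan lines at 0.45 mm
spacing along the focal arc cover the lesion plus flanking background.

## Imaging and metrics

`das_beamform()` is conventional delay-and-sum at a uniform speed (default
1540 m/s), one line per transmit, full receive aperture, linear
interpolation in time. By default it beamforms the *analytic* channel
signal (Hilbert transform applied to the densely sampled RF traces), so
the complex image modulus is the envelope; an image-domain Hilbert on
eighth-wavelength pixels would leak energy from strong echoes into quiet
regions. Axial pixels are an eighth of a wavelength, scan lines follow the
transmit angles.

* `psf_region_masks()` partitions an image deterministically: pixels map
  to a two-way time `2 d / c_bf`; the isochronous band is
  `[t_min - T, t_max + T]` with `t_min`, `t_max` the extreme
  element–target–element two-way times and `T` one pulse length.
  `region_magnitudes()` reports mean dB per region relative to the main
  lobe (the maximum *inside* the isochronous mask, so pre-isochronous
  clutter cannot corrupt the normalization); means are taken over dB
  pixels, and pixels whose beamformed time fell outside the record are
  excluded.
* `interelement_lags()` maximizes the normalized cross-correlation of
  adjacent elements in a window (default three pulse periods around each
  element's envelope peak), with FFT upsampling (8x) plus parabolic peak
  interpolation for sub-sample precision. `arrival_time_profile()`
  integrates the pairwise lags and removes the mean (bulk steering);
  `rms_aberration()` is the RMS profile difference against a
  homogeneous-medium reference, in nanoseconds. De-trending is mean
  removal only.
* `reverberation_curve()` averages the *linear* envelope laterally, then
  converts to dB.
* `coherence_curve()` receive-delays the channels to the transmit focus
  and averages the zero-lag correlation per element separation;
  `lag_one_coherence()` is its value at lag one.
* `cnr()` is `|mu_bg - mu_lesion| / sqrt(sigma_bg^2 + sigma_lesion^2)` on
  log-compressed pixels, with a not-detectable flag below 0.1 (the
  threshold is a package decision). The lesion ROI is the full lesion
  disc; the background is an equal-depth annulus 1.5–4.4 mm outside the
  lesion radius, within a ±4 mm depth band. ROIs are placed in *image*
  coordinates: beamforming at `c_bf` in a medium of speed `c0` displays a
  feature at true depth `z` at `z c_bf / c0`, and the ROI follows the
  imaged lesion, exactly as a manually drawn ROI would.

## Post-processing augmentation

Independently controlled degradation without re-simulation:

* `apply_phase_screen()` draws a zero-mean, laterally Gaussian-correlated
  delay profile (default correlation 5 elements), rescales it to the
  requested RMS *exactly*, and applies it per element as a frequency-domain
  fractional delay. Receive-side only; a two-way aberration requires
  re-simulation with modulated maps. Inverting the negated screen restores
  the input to machine precision.
* `scale_reverberation()` computes `rf - beta * rf_clutter`; the clutter
  record must be supplied (exact twin for simulated data, a wall-only
  acquisition otherwise) — clutter is never estimated blindly.
* `add_trailing_clutter()` convolves each channel, in depth blocks with
  overlap-add, with `delta(t) + A H(t) exp(-t/tau(z)) sin(2 pi f0 t)`,
  `tau(z)` ramping linearly from 0 at the surface to `tau_max` at the
  bottom of the record; no element-to-element variability.
* `isolate_and_scale_trailing()` aligns the emission reference with each
  channel's echo peak, classifies samples after the emission support
  (1% envelope threshold) as trailing, and scales them; applicable to
  point-target records.

At small magnitudes the three operations commute to within 1% RMS, and
each changes only its own metric — the separability thesis, asserted
operationally in the test suite.

## Study conditions used by the tests

Problem sizes were chosen so the whole quantitative suite runs on a single
CPU in well under half an hour:

* Lesion CNR study: 10 independent speckle realizations, 64 transmits
  each, grid about 510 x 360 at 131 µm, ~75 µs records.
* Separation study: one layered wall (12 mm thick, 2 mm peak roughness,
  6 mm interface correlation, sub-resolution scatterers of 12% contrast
  inside the wall), point targets at 35/41/47 mm and reflectivities
  0.05–0.93, each as a matched full/clutter pair plus homogeneous
  references.
* The interface correlation length is deliberately long relative to the
  aperture so that the effective phase screen is sampled consistently by
  targets at different depths; rough short-correlation walls make the
  measured RMS depth-dependent through pure ray geometry.
* The gamma-scaling demonstrations use walls whose reverberation is
  non-negligible at the lesion depth (thicker wall, stronger internal
  scattering); with a weakly reverberating wall the lesion CNR is simply
  insensitive to gamma at this scale.

## Limitations

2D only; linear and lossless (no attenuation, no harmonics); second-order
spatial accuracy with the dispersion noted above; staggered-grid
interface discretization produces small spurious reflections at strong
density steps (the clutter-subtraction route is exact regardless, because
the paired runs share them); receive-side phase screens are a one-way
idealization of two-way aberration; and the synthetic wall reproduces
aggregate statistics, not anatomy.
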