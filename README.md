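# usdecon

Deconstruction and reconstruction of medium-dependent ultrasound image
degradation.

Abdominal B-mode images are degraded by three distinct mechanisms: phase
aberration (sound-speed heterogeneity distorting the ballistic pulse),
multiple-reverberation clutter (energy bouncing between shallow tissue
layers that overlays deeper echoes without ever touching the target), and
trailing clutter (forward-scattered energy that travels with the pulse,
lengthens it, and is reflected by the target). They degrade images in
different ways — aberration is independent of target brightness,
reverberation's impact depends on it, trailing clutter scales with target
reflectivity — so strategies to correct them need tools that can isolate
each one. `usdecon` provides those tools for simulation studies and for
physics-based augmentation of RF data sets (e.g. machine-learning
training data with known, independently controlled degradation levels).

The package is aimed at ultrasound imaging researchers: it contains

* **Phantoms** — layered abdominal walls (fat/muscle/connective with
  rough random interfaces), sub-resolution scatterer fields at a
  prescribed density per resolution cell, anechoic lesions, and point
  targets of prescribed reflectivity `r = |Z_b − Z_t|/(Z_b + Z_t)`.
* **Map-modulation algebra** — isovelocity maps (`c ≡ c0`,
  `ρ_iv = Z_ref/c0`: aberration removed, impedance and hence
  reverberation preserved exactly), isoimpedance maps (`c = c_ref`,
  `ρ_ii = Z0/c_ref`: reverberation removed, aberration preserved), and a
  continuous two-parameter family
  `c_m = c0 + ζ(c_ref − c0)`, `ρ_m = (Z0 + γ Z′)/c_m` with
  `Z′ = ρ_ref c_m − Z0`, where `γ` scales reverberation and `ζ` scales
  aberration independently (γ = ζ = 1 is the identity; γ = ζ = 0
  homogenizes to `c0 = 1570 m/s`, `ρ0 = 1064 kg/m³`, `Z0 = 1.67 MRayl`).
* **A desk-scale 2D acoustic simulator** — linear, lossless,
  staggered-grid pressure–velocity finite differences with heterogeneous
  density, a convex-array source, absorbing sponge boundaries, and an
  Rcpp kernel fast enough that a focused transmit completes in under a
  second.
* **Imaging** — delay-and-sum beamforming (one line per transmit, IQ
  envelope), sector-scan assembly, log compression.
* **Separation** — exact clutter subtraction from matched
  with/without-target simulation pairs, deterministic PSF region masks
  (pre-isochronous / isochronous / trailing), and region magnitude
  statistics.
* **Metrics** — RMS phase aberration from adjacent-element
  cross-correlation arrival-time profiles, reverberation curves,
  spatial and lag-one coherence, speckle brightness, and lesion
  contrast-to-noise ratio (CNR, on log-compressed pixels).
* **Augmentation** — receive-side phase screens of exact requested RMS,
  reverberation scaling by clutter subtraction ratio β, and
  depth-dependent damped-sinusoid trailing kernels; all invertible or
  exactly parameterized, all seeded.

## A worked example

```r
library(usdecon)

## homogenize a heterogeneous map and check the equilibrium impedance
maps <- generate_layered_abdomen(domain = c(40e-3, 30e-3), dx = 2e-4,
                                 wall_thickness = 15e-3, seed = 1)
hom <- modulate_maps(maps, modulation_params(gamma = 0, zeta = 0))

## a point target under an aberrating wall: simulate matched pairs,
## subtract clutter, estimate the aberration strength
st  <- psf_separation_study(target_depths = 41e-3, reflectivities = 0.5)
d   <- st$depth[[1]]
sub <- subtract_clutter(d$full, d$clutter)
ref <- subtract_clutter(d$homog, d$homog_clutter)
estimate_rms_aberration(sub, ref)

## augment the clean reference with a 20 ns phase screen and recover it
ab <- apply_phase_screen(ref, screen_rms = 20, corr_len = 5, seed = 2)
estimate_rms_aberration(ab, ref)
```

Output:

```
homogenized: c = 1570 m/s, rho = 1064 kg/m^3, Z = 1.67 MRayl
RMS aberration through the wall: 46.3 ns
recovered screen RMS: 20.0 ns (requested 20)
```

The first line is the γ = ζ = 0 homogenization limit of the modulation
algebra. The second is the strength of the phase aberration accumulated
through the synthetic 12 mm body wall, measured exactly as on real data:
cross-correlating adjacent element signals of the clutter-subtracted
point-target record against a homogeneous-medium reference. The third
shows the augmentation round trip: a receive-side phase screen with an
exactly rescaled 20 ns RMS is applied in post-processing and recovered by
the same estimator to within a few percent.

A command-line front end wrapping the same functions
(`phantom`, `simulate`, `beamform`, `separate`, `metrics`, `augment`,
`run`) is installed at `inst/cli/usdecon.R`.

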