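---
title: "Simulating light-sheet illumination: model, metrics and design choices"
author: "lightSheetSim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating light-sheet illumination: model, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lightSheetSim)
```

# The problem

Light-sheet fluorescence microscopy (LSFM) excites fluorescence in a thin
planar region and images it orthogonally with a camera. How the sheet is
formed matters: a static cylindrical-lens sheet (SPIM) and a scanned
circular pencil beam (DSLM) both deliver photons travelling in nearly one
direction, so any refractive occlusion — a lipid droplet, an air bubble, a
bead — casts a persistent streak shadow. Two remedies exist: pivoting the
sheet during the exposure (mSPIM), which time-averages the shadows but is
incompatible with confocal line detection, and giving the scanned pencil
beam *passive* in-plane angular diversity by making it elliptical
(NA_y > NA_x; mDSLM), which keeps the rolling-shutter slit usable.

This package simulates all four architectures end to end — beam, phantom,
propagation, detection, scanning, tiling — so the illumination trade-offs
(shadowing vs field flatness vs slit compatibility) can be quantified in
silico.

# The physical model

## Beam geometry (closed form)

An elliptical Gaussian beam propagating along z is parameterized per axis
by a numerical aperture. The design formulas, implemented exactly as used
for quoting system parameters (vacuum wavelength, no medium factor):

$$\omega_{0} = \frac{\lambda}{\pi \mathrm{NA}}, \qquad
  z_R = \frac{\pi \omega_0^2}{\lambda}, \qquad
  \omega(z) = \omega_0\sqrt{1 + (z/z_R)^2},$$

$$I(x,y,z) = \frac{2}{\pi\,\omega_x \omega_y}
  \exp\!\left[-2\left(\frac{x^2}{\omega_x^2} +
  \frac{y^2}{\omega_y^2}\right)\right],$$

with both waists co-located at the focus. `beamWaist()`, `rayleighRange()`,
`beamRadius()` and `beamIntensity()` expose these; `pivotHalfAngle()` maps
an in-sheet NA to the equivalent sheet-pivot half-angle via
$\arcsin(\mathrm{NA})$ (0.18 ↦ 10.4°), and `slitWidthRule()` implements the
conventional slit sizing $1.5\sqrt{2}\,\omega_{0,y}$ of the reference
circular beam. Note one deliberate asymmetry: these *design* formulas use
the vacuum wavelength (so the standard NA 0.06 sheet has a quoted confocal
parameter $2z_R \approx 117\,\mu m$), whereas the wave propagation below is
carried out in the medium, where the same beam physically has
$z_R^{med} = n\,\pi\omega_0^2/\lambda \approx 85\,\mu m$. Wherever a metric
depends on where the beam has *actually* expanded by $\sqrt 2$ (the field
edges of `edgeRolloff()`), the in-medium value is used.

## Wave propagation

`propagateBeam()` advances a scalar complex field with the split-step
(beam-propagation) method: an exact non-paraxial angular-spectrum
diffraction step over one axial voxel in the homogeneous background
(carrier $k = 2\pi n_{bg}/\lambda$, evanescent band hard-truncated),
followed by a thin phase screen
$\exp[i k_0 (n(x,y,z) - n_{bg})\,\Delta z]$ wherever a slice intersects a
sphere, followed by a super-Gaussian absorbing boundary over the outer 10%
of the transverse grid. The first step advances half a voxel so that all
records and screens sit at slice centres. Sources are built by defining the
analytic waist field at the focus and numerically back-propagating it to
the entry face — no explicit astigmatic phase formula is needed, and the
construction is exact for the propagator in use.

Validation is part of the test suite: in homogeneous medium the fitted
$1/e^2$ radii track the analytic envelope (with the in-medium Rayleigh
range) to well under 2% over $\pm 2 z_R$, per-slice power is conserved to
machine precision before light reaches the absorber, and a run normalized
by itself is exactly 1.

## Phantoms

A `Phantom` is a background gel (default n = 1.46, an index-matched
TDE-cleared agarose) containing glass spheres (default n = 1.59,
polystyrene). Voxelization is lazy (slice by slice), deterministic, and
hard-edged: a voxel belongs to a sphere iff its centre lies inside it.
`occlusionPhantom()` ships the single-20-µm-sphere geometry (depth 125 µm,
2 µm off the beam axis, focus at 350 µm); `beadFieldPhantom()` draws a
seeded random field of 6-µm spheres at volume fraction 0.001 — the 0.1%
w/v bead loading of the corresponding physical phantom. The fluorophore
map F is 1 in dyed gel and 0 inside non-fluorescent spheres; for
fluorescent-bead phantoms it is inverted with a configurable background
ratio.

## Detection and image formation

The camera looks along x and records the yz plane. The detected image is
$S = (I \times F) \otimes C$ evaluated on the camera plane x = 0, where C
is the collection PSF of the NA 0.40 objective at 680 nm. Two PSF models
are available:

* `gaussian-approx` (default): separable Gaussian, lateral
  $\sigma = 0.21\,\lambda_{em}/\mathrm{NA}$, axial
  $\sigma = 0.66\,n\,\lambda_{em}/\mathrm{NA}^2$. This model *optically
  sections*: out-of-plane (x-displaced) light is down-weighted.
* `scalar-defocus`: kernels built from defocused-pupil scalar diffraction,
  each defocus slice carrying equal energy — the laterally
  energy-conserving behaviour of a real widefield camera, which does not
  section.

The distinction is not cosmetic. Metrics read at a fixed camera plane
depend on how the model treats light that an occlusion has redistributed
along x: the sectioning model reports deeper occlusion dips and a larger
defocus contribution to the field-edge roll-off. Normalization identities
and beam *orderings* hold under both models (asserted in the tests), but
absolute occlusion metrics are model-dependent; the package default
follows the Gaussian-approximation convention throughout.

In confocal-line mode each beam-position image is masked by a hard
rectangular slit of width $\omega_{slit}$ (scenario default 20 µm) centred
on the beam, then all positions are summed; normalization by the identical
sphere-free acquisition happens after summation. Full-scale runs never
materialize a 3D intensity volume: `propagateBeam()` streams the
detection-weighted x-projection slice by slice.

# Acquisition modes, sweeps, tiling

`runAcquisition()` implements SPIM (static flat-top sheet, widefield),
mSPIM (incoherent average over a pivot set; default 21 angles spanning
±10°, the time-average surrogate of a sawtooth pivot), and DSLM/mDSLM
(scanned pencil beams with slit detection). Scanned plans may restrict
full propagation to a window around the occluder and fill the remaining
positions with the y-shifted sphere-free image — exact for beams that
never feel the sphere. `runNASweep()` maps a metric over an (NA_x, NA_y)
grid; `runTiledZ()` advances the focus in axial steps (default 50 µm) and
stitches the in-focus bands, as in deep tiled acquisitions.

# Metrics

* `focusRatio()` / `focalIntensityRatio()` — normalized signal at the
  on-axis focal position (mean over a 3×3-pixel window), the occlusion
  statistic.
* `sigmaProfile()` — population standard deviation of normalized intensity
  across y per depth, the shadow-severity statistic; computed inside an
  analysis band that excludes the absorbing margin.
* `contrastProfile()` — Michelson contrast per 20-µm axial ROI, with
  1st/99th-percentile extrema by default (robust to single hot pixels; an
  exact-extrema switch exists for closed-form tests).
* `edgeRolloff()` — one minus the ratio of the scanned slit-summed signal
  at $z_{focus} \pm n z_R$ to the focal signal. It decomposes into slit
  clipping of the y-expanded beam plus a detection-defocus term that is
  common to all beams under the sectioning PSF; widening the slit removes
  only the first part (both behaviours are asserted in the tests).
* `attenuationCorrect()` — median intensity per depth, symmetric
  moving-average smoothing (10 pixels), ordinary least squares on the log,
  correction by $e^{+\mu_s z}$; $\mu_s$ reported in mm⁻¹. The window is
  symmetric with edge shrinking because a trailing window biases the
  fitted slope of an exponential by several 10⁻³ mm⁻¹ — above the
  idempotence tolerance the correction is held to.

# Numerical choices

* **Sampling rule.** A source is accepted when the grid resolves its
  angular bandwidth: pitch ≤ λ/(2 NA) per axis. (A waist-in-pixels rule
  would wrongly reject high-NA_y beams whose waist is sub-pixel but whose
  spectrum is well inside Nyquist; the focal spot then simply forms
  between pixels, and every reported metric is a ratio of identically
  sampled runs.)
* **Step size.** The propagation step equals the axial voxel pitch; a
  finer step means a finer phantom grid, keeping the phase screens aligned
  with the voxelization.
* **Ties and edges.** Sphere voxelization ties go to the nearest sphere
  (earlier spheres win exact ties); slit masks include pixels whose
  centres lie inside; scan positions must be whole pixels so that
  shift-invariance is exact.
* **Presets.** `presetGrid()` ships three problem sizes: `full` (0.25-µm
  voxels, 300-µm transverse extent), `scaled` (0.5 µm / 150 µm — used by
  `scripts/acceptance.R`), and `coarse` (1 µm / 120 µm — used by the
  package's own test-suite simulations). The occlusion metrics move by
  only a few percent between `coarse` and `scaled`; the scenario geometry
  is identical in all three.

# What the wave model does and does not reproduce

The simulator is a coherent scalar model with ideal spheres, an ideal
slit, and no noise. Its phantoms emulate index-matched gels with
monodisperse polystyrene beads; they do not model bead polydispersity,
sub-micron lipid scatterers, partial coherence, camera noise or
pixelation, or rolling-shutter timing. Passing tests therefore demonstrate
internal physical consistency (energy conservation, analytic envelopes,
normalization identities, metric algebra) and the *relative* behaviour of
the architectures under ideal coherent illumination — not quantitative
agreement with any particular physical instrument.

Two model behaviours deserve emphasis, because they are genuine physics of
the coherent model rather than bugs, and the acceptance checks measure
them:

* **Occlusion healing saturates.** Behind the 20-µm sphere, the elliptical
  0.06/0.18 beam keeps roughly 40–50% of its focal intensity (the circular
  beam keeps under 10%). The improvement is real but bounded: the sphere
  intercepts essentially the whole NA_x aperture, and the focal field is
  the coherent integral over the full two-dimensional aperture, so no
  amount of in-plane angular diversity can recover the amplitude lost from
  the out-of-plane axis. The recovery grows monotonically with NA_y
  (asserted as a trend test over NA_y up to 0.24) but remains well short
  of full recovery across that range.
* **Small-sphere fields under coherent light are caustic-dominated.** In
  the seeded 6-µm bead field, each bead acts as a micro ball-lens on the
  beam; near the sheet focus the elliptical beam's 1.2-µm spot is captured
  whole by a bead, producing bright caustics and deep dips. The
  y-fluctuation statistic σ_I,y then reflects caustic contrast as much as
  accumulated shadowing, and at shallow depths the elliptical beam can
  fluctuate *more* than the circular one; the shadow-accumulation
  advantage of the elliptical beam is a deep-sample, partially incoherent
  effect that an ideal coherent simulation understates.

# Reproducibility

Every stochastic element (bead placement, synthetic noise) is seeded, and
generators restore the caller's RNG state. Run configurations round-trip
losslessly through YAML (`loadConfig()`/`saveConfig()`), stacks are
written as 32-bit TIFF with a metadata sidecar (`writeStack()`), metric
tables as CSV with a provenance header (`writeMetricTable()`), and every
CLI run writes a JSON manifest with the config hash
(`writeRunManifest()`). `scripts/acceptance.R` recomputes the headline
occlusion and field-flatness numbers from scratch on the scaled preset.
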