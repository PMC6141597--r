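# lightSheetSim

Physical-optics simulation of illumination in light-sheet fluorescence
microscopy (LSFM), for microscope designers and computational imaging
researchers who want to quantify — before building anything — how an
illumination architecture trades off shadowing artifacts, field flatness
and compatibility with confocal line detection.

The package simulates the four classical LSFM illumination schemes:

| mode  | illumination                         | detection        |
|-------|--------------------------------------|------------------|
| SPIM  | static 2D sheet                      | widefield        |
| mSPIM | sheet pivoted in-plane (time-averaged) | widefield      |
| DSLM  | scanned circular pencil beam         | confocal slit    |
| mDSLM | scanned *elliptical* pencil beam     | confocal slit    |

The elliptical (decoupled-NA) beam is the interesting one: its in-sheet
numerical aperture NA_y sets the angular diversity available to fill in
shadows behind refractive occlusions, while the out-of-plane NA_x keeps
the sheet thin over a long depth of focus.

## The model

**Beam geometry.** An elliptical Gaussian beam with per-axis waists and
Rayleigh ranges

ω₀ = λ/(π·NA),  z_R = π·ω₀²/λ,  ω(z) = ω₀·√(1 + (z/z_R)²),

I(x,y,z) = 2/(π·ω_x·ω_y) · exp[−2(x²/ω_x² + y²/ω_y²)].

**Propagation.** Split-step scalar beam propagation (BPM): non-paraxial
angular-spectrum diffraction through the background medium (carrier
k = 2πn/λ), thin phase screens exp[i·k₀·(n−n_bg)·Δz] for the voxelized
refractive phantom, super-Gaussian absorbing boundaries.

**Phantoms.** Glass microspheres (n = 1.59) in index-matched fluorescent
gel (n = 1.46): a single 20-µm occluder for shadow studies, seeded random
6-µm bead fields for accumulated-shadowing studies.

**Image formation.** S = (I·F) ⊗ C with the collection PSF of a 0.40-NA
objective (Gaussian approximation or scalar-defocus kernels), hard
rectangular confocal slit (20 µm) summed over scan positions, and
element-wise normalization by the identical sphere-free run.

**Metrics.** Normalized focal intensity behind an occluder, shadow
severity σ_I,y(z), Michelson contrast C(z) per 20-µm ROI, field-edge
roll-off at z_focus ± z_R,x, and exponential attenuation fitting
(I = e^(−μ_s z), μ_s in mm⁻¹) with flattening correction.

## Worked example

Design numbers for the standard beams (660 nm excitation), then the
single-sphere occlusion scenario — a 20-µm glass sphere at depth 125 µm,
2 µm off the beam axis, beam focused at 350 µm — on the fast preset:

```r
library(lightSheetSim)

beamWaist(0.06, 0.660)        # sheet-axis waist
beamWaist(0.18, 0.660)        # in-sheet waist of the elliptical beam
2 * rayleighRange(0.06, 0.660) # confocal parameter (depth of focus)
pivotHalfAngle(0.18)          # equivalent sheet-pivot half-angle

grid <- presetGrid("coarse", zExtent = 370)
occlusionFocalRatio(dslmBeam(),  preset = grid)
occlusionFocalRatio(mdslmBeam(), preset = grid)
```

Output:

```
w0x: 3.5 um
w0y: 1.17 um
2zR: 116.7 um
pivot: 10.4 deg
DSLM  focal ratio: 0.098 (reduction 90%)
mDSLM focal ratio: 0.297 (reduction 70%)
```

The circular beam loses ~90% of its focal intensity behind the sphere;
the elliptical beam, with three times the in-sheet angular diversity,
keeps about three times more signal at the focus. Scanned, slit-apertured
acquisitions (`occlusionScannedRatio()`), NA_x × NA_y design sweeps
(`runNASweep()`), tiled deep imaging (`runTiledZ()`) and the bead-field
shadowing statistic (`beadFieldPhantom()` + `sigmaProfile()`) build on the
same engine. A thin command-line front end lives in `inst/cli/lsim.R`
(`fixtures | beam | scan | sweep | tile | metrics` over YAML configs).

The methods vignette (`vignettes/illumination-simulation.Rmd`) documents
the propagation scheme, the detection-model choices and their
consequences, the numerical conventions, and what the coherent scalar
model does and does not reproduce about real instruments.

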