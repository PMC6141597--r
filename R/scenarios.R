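## Shipped scenario presets: the single-sphere occlusion geometry, the
## small-sphere field, and the grids they run on.

#' Preset simulation grids
#'
#' \describe{
#'   \item{full}{0.25-um voxels, 300-um transverse extent — the full-fidelity
#'     geometry (1200 x 1200 transverse; intended for workstation runs).}
#'   \item{scaled}{0.5-um voxels, 150-um transverse extent — the standard
#'     desk-scale preset used by the shipped analyses.}
#'   \item{coarse}{1-um voxels, 120-um transverse extent — the fast preset
#'     used by the package's own test-suite simulations.}
#' }
#'
#' @param preset "full", "scaled" or "coarse".
#' @param zExtent simulated depth, um (default 450 covers the sphere at
#'   125 um, the focus at 350 um and the field edges around it).
#' @return A [GridSpec-class].
#' @export
presetGrid <- function(preset = c("scaled", "coarse", "full"), zExtent = 450) {
    preset <- match.arg(preset)
    p <- switch(preset,
                full = list(pitch = 0.25, ext = 300),
                scaled = list(pitch = 0.5, ext = 150),
                coarse = list(pitch = 1.0, ext = 120))
    GridSpec(nx = round(p$ext / p$pitch), ny = round(p$ext / p$pitch),
             nz = round(zExtent / p$pitch), dx = p$pitch)
}

#' Standard beams
#'
#' The circular scanned-beam (DSLM, NA 0.06/0.06) and elliptical
#' multidirectional (mDSLM, NA 0.06/0.18) excitation beams at 660 nm in the
#' index-matched gel (n = 1.46).
#'
#' @return A [BeamSpec-class].
#' @export
dslmBeam <- function() BeamSpec(0.06, 0.06, wavelength = 0.660,
                                mediumIndex = 1.46)

#' @rdname dslmBeam
#' @export
mdslmBeam <- function() BeamSpec(0.06, 0.18, wavelength = 0.660,
                                 mediumIndex = 1.46)

#' Single-sphere occlusion phantom
#'
#' The large-sphere occlusion geometry: one glass sphere (d = 20 um,
#' n = 1.59) in index-matched fluorescent gel (n = 1.46), centred at depth
#' 125 um, offset 2 um from the beam axis along the scan direction, beam
#' focus at 350 um.
#'
#' @param grid a [GridSpec-class].
#' @param sphereZ,sphereY sphere centre depth and y offset, um.
#' @param diameter sphere diameter, um.
#' @param index sphere refractive index.
#' @param nGel gel refractive index.
#' @return A [Phantom-class].
#' @export
occlusionPhantom <- function(grid, sphereZ = 125, sphereY = 2, diameter = 20,
                             index = 1.59, nGel = 1.46) {
    buildPhantom(grid, nBackground = nGel,
                 spheres = list(SphereSpec(c(0, sphereY, sphereZ),
                                           diameter = diameter,
                                           index = index)))
}

#' Small-sphere field phantom
#'
#' A seeded random field of small glass spheres (default d = 6 um, n = 1.59)
#' in fluorescent gel — the in-silico analogue of the bead-loaded phantom
#' used to study accumulated shadowing.
#'
#' @param grid a [GridSpec-class].
#' @param seed integer seed.
#' @param diameter sphere diameter, um.
#' @param volumeFraction sphere volume fraction (default 0.001, the 0.1% w/v bead loading).
#' @param minGap minimum sphere gap, um.
#' @return A [Phantom-class].
#' @export
beadFieldPhantom <- function(grid, seed = 42L, diameter = 6,
                             volumeFraction = 0.001, minGap = 1) {
    randomSpherePhantom(grid, diameter = diameter,
                        volumeFraction = volumeFraction, seed = seed,
                        minGap = minGap,
                        edgeMargin = 0.1 * grid@ny * grid@dy)
}

#' Single-beam occlusion metric
#'
#' Runs the single static beam of the occlusion scenario and returns the
#' normalized focal intensity (1 = unobstructed). The percent reduction is
#' \code{100 * (1 - value)}.
#'
#' @param beam a [BeamSpec-class] (see [dslmBeam()], [mdslmBeam()]).
#' @param preset grid preset name, or a [GridSpec-class].
#' @param zFocus focus depth, um.
#' @param zExtent simulated depth, um.
#' @return Normalized focal intensity.
#' @export
occlusionFocalRatio <- function(beam, preset = "scaled", zFocus = 350,
                                zExtent = 370) {
    grid <- if (is(preset, "GridSpec")) preset else
        presetGrid(preset, zExtent = zExtent)
    ph <- occlusionPhantom(grid)
    singleBeamFocalRatio(beam, ph, zFocus)
}

#' Scanned confocal occlusion metric
#'
#' Runs the scanned, slit-apertured acquisition of the occlusion scenario
#' (beams propagated inside a +/- \code{window} um window around the sphere,
#' shift-invariant fill outside) and returns the normalized intensity at the
#' light-sheet focus.
#'
#' @param beam a [BeamSpec-class].
#' @param preset grid preset name or a [GridSpec-class].
#' @param zFocus focus depth, um.
#' @param zExtent simulated depth, um.
#' @param scanStep scan increment, um.
#' @param window full-propagation half-window, um.
#' @param slitWidth confocal slit width, um.
#' @return Normalized light-sheet-focus intensity.
#' @export
occlusionScannedRatio <- function(beam, preset = "scaled", zFocus = 350,
                                  zExtent = 370, scanStep = 2, window = 30,
                                  slitWidth = 20) {
    grid <- if (is(preset, "GridSpec")) preset else
        presetGrid(preset, zExtent = zExtent)
    ph <- occlusionPhantom(grid)
    mode <- if (beam@naY > beam@naX) "mDSLM" else "DSLM"
    plan <- AcquisitionPlan(mode, beam = beam,
                            detection = DetectionSpec(slitWidth = slitWidth),
                            zFocus = zFocus, scanStep = scanStep,
                            scanWindow = window,
                            windowCenter = 0)
    st <- runAcquisition(plan, ph)
    focusRatio(st, zFocus)
}

#' Field-edge roll-off of the standard scanned acquisition
#'
#' Sphere-free scanned confocal acquisition at the given beam; returns the
#' roll-off of the detected signal at the field edges relative to the focus
#' (see [edgeRolloff()]).
#'
#' @inheritParams occlusionScannedRatio
#' @return Roll-off fraction.
#' @export
fieldEdgeRolloff <- function(beam, preset = "scaled", zFocus = 350,
                             zExtent = 450, scanStep = 2, slitWidth = 20) {
    grid <- if (is(preset, "GridSpec")) preset else
        presetGrid(preset, zExtent = zExtent)
    ph <- buildPhantom(grid, nBackground = beam@mediumIndex)
    scannedEdgeRolloff(beam, ph, zFocus,
                       detection = DetectionSpec(slitWidth = slitWidth),
                       scanStep = scanStep)
}
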