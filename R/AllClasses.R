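#' @import methods
NULL

## ---------------------------------------------------------------------------
## BeamSpec
## ---------------------------------------------------------------------------

#' Excitation beam specification
#'
#' An elliptical Gaussian pencil beam is parameterized by two numerical
#' apertures: \code{naX} in the plane orthogonal to the light sheet (sets the
#' sheet thickness and depth of focus) and \code{naY} in the plane of the
#' sheet (sets the in-sheet angular diversity). The circular DSLM beam has
#' \code{naX == naY}; the multidirectional mDSLM beam has \code{naY > naX}.
#' \code{naY = 0} denotes a beam collimated in y (a static SPIM-style sheet).
#'
#' @slot naX numeric, numerical aperture along x (dimensionless).
#' @slot naY numeric, numerical aperture along y (dimensionless, may be 0).
#' @slot wavelength numeric, vacuum excitation wavelength in micrometres.
#' @slot mediumIndex numeric, refractive index of the immersion/background
#'   medium. Carried for the wave-propagation engine; the closed-form
#'   Gaussian-optics helpers use the vacuum wavelength as printed in the
#'   standard design formulas.
#'
#' @seealso [BeamSpec()], [beamWaist()], [rayleighRange()]
#' @export
setClass("BeamSpec",
    representation(naX = "numeric", naY = "numeric",
                   wavelength = "numeric", mediumIndex = "numeric"),
    prototype(naX = 0.06, naY = 0.06, wavelength = 0.660, mediumIndex = 1.46))

setValidity("BeamSpec", function(object) {
    msg <- character()
    if (length(object@naX) != 1 || !is.finite(object@naX) || object@naX <= 0)
        msg <- c(msg, "'naX' must be a single positive number")
    if (length(object@naY) != 1 || !is.finite(object@naY) || object@naY < 0)
        msg <- c(msg, "'naY' must be a single non-negative number")
    if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
        object@wavelength <= 0)
        msg <- c(msg, "'wavelength' must be a single positive number (um)")
    if (length(object@mediumIndex) != 1 || !is.finite(object@mediumIndex) ||
        object@mediumIndex <= 0)
        msg <- c(msg, "'mediumIndex' must be a single positive number")
    if (length(msg) == 0 &&
        max(object@naX, object@naY) >= object@mediumIndex)
        msg <- c(msg, "numerical apertures must be smaller than 'mediumIndex'")
    if (length(msg)) msg else TRUE
})

#' Construct a BeamSpec
#'
#' @param naX numerical aperture orthogonal to the sheet (> 0).
#' @param naY numerical aperture in the sheet plane (>= 0; 0 = collimated).
#' @param wavelength vacuum excitation wavelength, um.
#' @param mediumIndex refractive index of the background medium.
#' @return A [BeamSpec-class] object.
#' @examples
#' dslm  <- BeamSpec(0.06, 0.06)
#' mdslm <- BeamSpec(0.06, 0.18)
#' @export
BeamSpec <- function(naX, naY = naX, wavelength = 0.660, mediumIndex = 1.46) {
    new("BeamSpec", naX = as.numeric(naX), naY = as.numeric(naY),
        wavelength = as.numeric(wavelength),
        mediumIndex = as.numeric(mediumIndex))
}

## ---------------------------------------------------------------------------
## GridSpec
## ---------------------------------------------------------------------------

#' Simulation grid specification
#'
#' Voxel grid for phantoms and propagation. Conventions: z is the illumination
#' propagation axis with slice centres at (k - 1/2) * dz for k = 1..nz
#' (half-open [0, nz*dz)); x (detection axis) and y (scan axis) are centred on
#' the beam optical axis, with voxel centres at (i - (n+1)/2) * pitch.
#'
#' @slot nx,ny,nz integer voxel counts.
#' @slot dx,dy,dz numeric voxel pitches, um.
#' @export
setClass("GridSpec",
    representation(nx = "integer", ny = "integer", nz = "integer",
                   dx = "numeric", dy = "numeric", dz = "numeric"))

setValidity("GridSpec", function(object) {
    msg <- character()
    for (s in c("nx", "ny", "nz")) {
        v <- slot(object, s)
        if (length(v) != 1 || is.na(v) || v < 1)
            msg <- c(msg, sprintf("'%s' must be a single count >= 1", s))
    }
    for (s in c("dx", "dy", "dz")) {
        v <- slot(object, s)
        if (length(v) != 1 || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single positive pitch (um)", s))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nx,ny,nz voxel counts along x (detection), y (scan), z (propagation).
#' @param dx,dy,dz voxel pitches in um (dy, dz default to dx).
#' @return A [GridSpec-class] object.
#' @examples
#' g <- GridSpec(300, 300, 900, dx = 0.5)
#' @export
GridSpec <- function(nx, ny = nx, nz, dx, dy = dx, dz = dx) {
    new("GridSpec", nx = as.integer(nx), ny = as.integer(ny),
        nz = as.integer(nz), dx = as.numeric(dx), dy = as.numeric(dy),
        dz = as.numeric(dz))
}

#' Grid coordinate vectors
#'
#' Voxel-centre coordinates in um. x and y are centred on the optical axis;
#' z starts at dz/2 (half-open [0, nz*dz)).
#'
#' @param grid a [GridSpec-class].
#' @return Numeric vector of voxel-centre coordinates.
#' @export
xCoords <- function(grid) (seq_len(grid@nx) - (grid@nx + 1) / 2) * grid@dx

#' @rdname xCoords
#' @export
yCoords <- function(grid) (seq_len(grid@ny) - (grid@ny + 1) / 2) * grid@dy

#' @rdname xCoords
#' @export
zCoords <- function(grid) (seq_len(grid@nz) - 0.5) * grid@dz

## ---------------------------------------------------------------------------
## SphereSpec
## ---------------------------------------------------------------------------

#' Refractive sphere specification
#'
#' A glass microsphere embedded in the gel. Positions use the grid coordinate
#' convention of [GridSpec()]: x and y relative to the beam axis, z measured
#' from the illumination entry face.
#'
#' @slot center numeric length-3, (x, y, z) centre in um.
#' @slot diameter numeric, sphere diameter in um.
#' @slot index numeric, refractive index of the sphere.
#' @slot fluorescent logical; TRUE for dyed (fluorophore-filled) spheres.
#' @export
setClass("SphereSpec",
    representation(center = "numeric", diameter = "numeric",
                   index = "numeric", fluorescent = "logical"))

setValidity("SphereSpec", function(object) {
    msg <- character()
    if (length(object@center) != 3 || any(!is.finite(object@center)))
        msg <- c(msg, "'center' must be a finite (x, y, z) triple")
    if (length(object@diameter) != 1 || !is.finite(object@diameter) ||
        object@diameter <= 0)
        msg <- c(msg, "'diameter' must be a single positive number (um)")
    if (length(object@index) != 1 || !is.finite(object@index) ||
        object@index <= 0)
        msg <- c(msg, "'index' must be a single positive refractive index")
    if (length(object@fluorescent) != 1 || is.na(object@fluorescent))
        msg <- c(msg, "'fluorescent' must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' Construct a SphereSpec
#'
#' @param center numeric (x, y, z) centre, um.
#' @param diameter sphere diameter, um.
#' @param index sphere refractive index (polystyrene/glass beads: 1.59).
#' @param fluorescent logical, whether the sphere carries fluorophore.
#' @return A [SphereSpec-class] object.
#' @examples
#' SphereSpec(c(0, 2, 125), diameter = 20, index = 1.59)
#' @export
SphereSpec <- function(center, diameter, index = 1.59, fluorescent = FALSE) {
    new("SphereSpec", center = as.numeric(center),
        diameter = as.numeric(diameter), index = as.numeric(index),
        fluorescent = as.logical(fluorescent))
}

## ---------------------------------------------------------------------------
## Phantom
## ---------------------------------------------------------------------------

#' Voxelized refractive-index and fluorophore phantom
#'
#' A phantom is a background gel of index \code{nBackground} containing a list
#' of [SphereSpec-class] spheres. The voxelized refractive index n(x,y,z) and
#' fluorophore map F(x,y,z) are evaluated lazily, slice by slice (see
#' [refractiveSlice()]), so full-scale volumes never need to be materialized;
#' [refractiveVolume()] materializes small volumes for inspection and export.
#'
#' A voxel takes a sphere's index iff its centre lies inside the sphere
#' (hard boundary, no anti-aliasing; ties go to the nearest sphere, earlier
#' spheres winning exact ties). The fluorophore map is \code{1} in fluorescent
#' gel outside spheres and \code{0} inside non-fluorescent spheres; for
#' fluorescent-sphere phantoms (non-fluorescent gel) F is 1 inside the spheres
#' and \code{fluorBackground} outside.
#'
#' @slot grid a [GridSpec-class].
#' @slot nBackground background (gel) refractive index.
#' @slot spheres list of [SphereSpec-class].
#' @slot gelFluorescent logical; TRUE when the gel itself is dyed.
#' @slot fluorBackground numeric in [0, 1]; gel fluorophore level used when
#'   \code{gelFluorescent} is FALSE (the dye bleed-through ratio).
#' @slot seed integer or NA; the seed used by [randomSpherePhantom()].
#' @export
setClass("Phantom",
    representation(grid = "GridSpec", nBackground = "numeric",
                   spheres = "list", gelFluorescent = "logical",
                   fluorBackground = "numeric", seed = "integer"))

setValidity("Phantom", function(object) {
    msg <- character()
    if (length(object@nBackground) != 1 || !is.finite(object@nBackground) ||
        object@nBackground <= 0)
        msg <- c(msg, "'nBackground' must be a single positive index")
    if (!all(vapply(object@spheres, is, logical(1), "SphereSpec")))
        msg <- c(msg, "'spheres' must be a list of SphereSpec objects")
    if (length(object@fluorBackground) != 1 ||
        !is.finite(object@fluorBackground) ||
        object@fluorBackground < 0 || object@fluorBackground > 1)
        msg <- c(msg, "'fluorBackground' must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FieldSlice
## ---------------------------------------------------------------------------

#' Complex transverse field slice
#'
#' The scalar field u(x, y) on one transverse plane during propagation,
#' stored as a complex \code{nx x ny} matrix (rows = x, columns = y), with
#' the carrier wavenumber k = 2 pi * mediumIndex / wavelength implied by its
#' beam parameters.
#'
#' @slot field complex matrix, u(x, y).
#' @slot dx,dy transverse pitches, um.
#' @slot wavelength vacuum wavelength, um.
#' @slot mediumIndex background refractive index used as the carrier.
#' @slot z axial position of the slice, um.
#' @export
setClass("FieldSlice",
    representation(field = "matrix", dx = "numeric", dy = "numeric",
                   wavelength = "numeric", mediumIndex = "numeric",
                   z = "numeric"))

setValidity("FieldSlice", function(object) {
    msg <- character()
    if (!is.complex(object@field))
        msg <- c(msg, "'field' must be a complex matrix")
    else if (any(!is.finite(Re(object@field))) ||
             any(!is.finite(Im(object@field))))
        msg <- c(msg, "'field' contains non-finite values")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## PropagationConfig
## ---------------------------------------------------------------------------

#' Beam-propagation configuration
#'
#' @slot beam a [BeamSpec-class].
#' @slot zFocus depth of the beam focus, um (measured from the entry face).
#' @slot dz axial step, um (defaults to the grid's axial pitch).
#' @slot boundaryFraction fraction of the transverse grid (per edge) covered
#'   by the absorbing super-Gaussian boundary, in [0, 0.25].
#' @slot sourceType one of "pencil", "sheet" (flat-top in y) or
#'   "pivoted-sheet" (tilted sheet, used by the mSPIM mode).
#' @slot recordPlan character vector naming the records to keep; any of
#'   "axial" (on-axis intensity patch per slice), "planeYZ" (the x = 0 plane),
#'   "camera" (the detection-weighted x-projection used for image formation),
#'   "power" (per-slice total power), "radii" (second-moment 1/e^2 radii),
#'   "focalPlane" (the transverse plane nearest the focus).
#' @slot detection a [DetectionSpec-class] or NULL; required for "camera".
#' @slot sourceY beam displacement along the scan axis, um.
#' @slot pivotAngle sheet tilt in degrees (pivoted-sheet source only).
#' @slot fieldWidthY flat-top sheet width, um (sheet sources; NA = full field).
#' @export
setClass("PropagationConfig",
    representation(beam = "BeamSpec", zFocus = "numeric", dz = "numeric",
                   boundaryFraction = "numeric", sourceType = "character",
                   recordPlan = "character", detection = "ANY",
                   sourceY = "numeric", pivotAngle = "numeric",
                   fieldWidthY = "numeric"))

setValidity("PropagationConfig", function(object) {
    msg <- character()
    if (!is.na(object@dz) && object@dz <= 0)
        msg <- c(msg, "'dz' must be positive")
    if (object@boundaryFraction < 0 || object@boundaryFraction > 0.25)
        msg <- c(msg, "'boundaryFraction' must lie in [0, 0.25]")
    if (!object@sourceType %in% c("pencil", "sheet", "pivoted-sheet"))
        msg <- c(msg, "'sourceType' must be pencil, sheet or pivoted-sheet")
    known <- c("axial", "planeYZ", "camera", "power", "radii", "focalPlane")
    bad <- setdiff(object@recordPlan, known)
    if (length(bad))
        msg <- c(msg, paste0("unknown recordPlan entries: ",
                             paste(bad, collapse = ", ")))
    if ("camera" %in% object@recordPlan && is.null(object@detection))
        msg <- c(msg, "'camera' record requires a DetectionSpec")
    if (length(msg)) msg else TRUE
})

#' Construct a PropagationConfig
#'
#' @param beam a [BeamSpec-class].
#' @param zFocus focus depth, um.
#' @param dz axial step, um; NA means "use the grid's dz".
#' @param boundaryFraction absorbing-boundary width as a fraction of the
#'   transverse grid per edge.
#' @param sourceType "pencil", "sheet" or "pivoted-sheet".
#' @param recordPlan which per-slice records to keep (see
#'   [PropagationConfig-class]).
#' @param detection optional [DetectionSpec-class] (needed for "camera").
#' @param sourceY beam displacement along y, um.
#' @param pivotAngle sheet tilt, degrees.
#' @param fieldWidthY flat-top sheet width, um.
#' @return A [PropagationConfig-class] object.
#' @export
PropagationConfig <- function(beam, zFocus, dz = NA_real_,
                              boundaryFraction = 0.1,
                              sourceType = "pencil",
                              recordPlan = c("axial", "power"),
                              detection = NULL, sourceY = 0,
                              pivotAngle = 0, fieldWidthY = NA_real_) {
    new("PropagationConfig", beam = beam, zFocus = as.numeric(zFocus),
        dz = as.numeric(dz), boundaryFraction = as.numeric(boundaryFraction),
        sourceType = sourceType, recordPlan = recordPlan,
        detection = detection, sourceY = as.numeric(sourceY),
        pivotAngle = as.numeric(pivotAngle),
        fieldWidthY = as.numeric(fieldWidthY))
}

## ---------------------------------------------------------------------------
## IntensityRecord
## ---------------------------------------------------------------------------

#' Recorded illumination intensity
#'
#' Per-slice records streamed out of [propagateBeam()]. Only the planes and
#' statistics named in the propagation record plan are kept, so full-scale
#' intensity volumes are never required in memory.
#'
#' @slot grid the [GridSpec-class] of the run.
#' @slot axial numeric array (wx x wy x nz): intensity patch around the beam
#'   axis per slice, or empty.
#' @slot planeYZ numeric matrix (ny x nz): the yz plane at x = 0 (mean of the
#'   two centre rows on even grids), or empty.
#' @slot camera numeric matrix (ny x nz): detection-weighted x-projection of
#'   I * F (the pre-blur camera accumulator), or empty.
#' @slot power numeric nz: per-slice transverse power.
#' @slot radii numeric matrix (nz x 2): second-moment 1/e^2 radii (wx, wy).
#' @slot focalPlane numeric matrix (nx x ny) at the slice nearest the focus.
#' @slot meta list of provenance (config echo, source power, slit, etc.).
#' @export
setClass("IntensityRecord",
    representation(grid = "GridSpec", axial = "array", planeYZ = "matrix",
                   camera = "matrix", power = "numeric", radii = "matrix",
                   focalPlane = "matrix", meta = "list"))

## ---------------------------------------------------------------------------
## DetectionSpec
## ---------------------------------------------------------------------------

#' Fluorescence detection specification
#'
#' Detection is orthogonal to the illumination: the collection objective looks
#' along x and images the yz plane. The detected image is the excited
#' fluorescence (I * F) convolved with the collection PSF and evaluated on the
#' camera focal plane x = 0; in confocal-line mode each beam-position image is
#' additionally masked by a hard rectangular slit of width \code{slitWidth}
#' centred on the beam before summation.
#'
#' @slot na collection numerical aperture.
#' @slot lambdaEm emission wavelength, um.
#' @slot psfModel "gaussian-approx" (separable Gaussian, lateral
#'   sigma = latC * lambdaEm / NA, axial sigma = axC * n * lambdaEm / NA^2) or
#'   "scalar-defocus" (defocused-pupil diffraction kernels).
#' @slot slitWidth confocal slit width, um (full width).
#' @slot mode "widefield" or "confocal-line".
#' @slot pixelPitch camera pixel pitch referred to sample space, um.
#' @slot latC,axC the Gaussian-approximation constants (defaults 0.21, 0.66).
#' @slot mediumIndex immersion index used by the axial PSF extent.
#' @export
setClass("DetectionSpec",
    representation(na = "numeric", lambdaEm = "numeric", psfModel = "character",
                   slitWidth = "numeric", mode = "character",
                   pixelPitch = "numeric", latC = "numeric", axC = "numeric",
                   mediumIndex = "numeric"))

setValidity("DetectionSpec", function(object) {
    msg <- character()
    if (object@na <= 0 || object@na >= object@mediumIndex)
        msg <- c(msg, "'na' must satisfy 0 < na < mediumIndex")
    if (object@lambdaEm <= 0)
        msg <- c(msg, "'lambdaEm' must be positive (um)")
    if (!object@psfModel %in% c("gaussian-approx", "scalar-defocus"))
        msg <- c(msg, "'psfModel' must be gaussian-approx or scalar-defocus")
    if (!object@mode %in% c("widefield", "confocal-line"))
        msg <- c(msg, "'mode' must be widefield or confocal-line")
    if (object@mode == "confocal-line" &&
        (!is.finite(object@slitWidth) || object@slitWidth <= 0))
        msg <- c(msg, "'slitWidth' must be positive in confocal-line mode")
    if (length(msg)) msg else TRUE
})

#' Construct a DetectionSpec
#'
#' Defaults follow the simulated collection arm: NA 0.40, emission 0.680 um,
#' 20-um confocal slit.
#'
#' @param na collection NA.
#' @param lambdaEm emission wavelength, um.
#' @param psfModel "gaussian-approx" or "scalar-defocus".
#' @param slitWidth slit full width, um.
#' @param mode "widefield" or "confocal-line".
#' @param pixelPitch sample-referenced camera pixel pitch, um.
#' @param latC,axC Gaussian PSF constants.
#' @param mediumIndex immersion refractive index.
#' @return A [DetectionSpec-class] object.
#' @examples
#' DetectionSpec()                      # confocal-line, 20-um slit
#' DetectionSpec(mode = "widefield")
#' @export
DetectionSpec <- function(na = 0.40, lambdaEm = 0.680,
                          psfModel = "gaussian-approx", slitWidth = 20,
                          mode = "confocal-line", pixelPitch = 0.77,
                          latC = 0.21, axC = 0.66, mediumIndex = 1.46) {
    new("DetectionSpec", na = as.numeric(na), lambdaEm = as.numeric(lambdaEm),
        psfModel = psfModel, slitWidth = as.numeric(slitWidth), mode = mode,
        pixelPitch = as.numeric(pixelPitch), latC = as.numeric(latC),
        axC = as.numeric(axC), mediumIndex = as.numeric(mediumIndex))
}

## ---------------------------------------------------------------------------
## CameraImage / AcquiredStack
## ---------------------------------------------------------------------------

#' Detected camera image
#'
#' A 2D image in the yz plane (rows = y, columns = z) as seen by the camera
#' looking along x.
#'
#' @slot image numeric ny x nz matrix.
#' @slot dy,dz pixel pitches, um.
#' @slot provenance list (mode, beam position(s), slit, normalization state).
#' @export
setClass("CameraImage",
    representation(image = "matrix", dy = "numeric", dz = "numeric",
                   provenance = "list"))

#' Acquired (possibly normalized, possibly tiled) image stack
#'
#' The output of [runAcquisition()] and [runTiledZ()]: a yz image (rows = y,
#' columns = z), its pitches, whether it has been normalized by the matching
#' sphere-free reference, and per-run provenance.
#'
#' @slot image numeric ny x nz matrix.
#' @slot dy,dz pixel pitches, um.
#' @slot normalized logical.
#' @slot provenance list (mode, plan echo, tile boundaries, reference id).
#' @export
setClass("AcquiredStack",
    representation(image = "matrix", dy = "numeric", dz = "numeric",
                   normalized = "logical", provenance = "list"))

setValidity("AcquiredStack", function(object) {
    if (any(!is.finite(object@image)))
        "stack image contains non-finite values" else TRUE
})

## ---------------------------------------------------------------------------
## AcquisitionPlan
## ---------------------------------------------------------------------------

#' Acquisition plan for the four light-sheet architectures
#'
#' \describe{
#'   \item{SPIM}{static flat-top sheet, widefield detection.}
#'   \item{mSPIM}{incoherent average of pivoted sheets, widefield detection.}
#'   \item{DSLM}{scanned circular pencil beam, confocal-line detection.}
#'   \item{mDSLM}{scanned elliptical pencil beam, confocal-line detection.}
#' }
#' DSLM and mDSLM plans differ only in their [BeamSpec-class]; SPIM and mSPIM
#' only in the pivot set.
#'
#' @slot mode one of "SPIM", "mSPIM", "DSLM", "mDSLM".
#' @slot beam a [BeamSpec-class].
#' @slot detection a [DetectionSpec-class].
#' @slot zFocus focus depth, um.
#' @slot scanStep y scan increment, um (scanned modes; must be a multiple of
#'   the grid's dy).
#' @slot scanRange length-2 numeric, y scan start/stop, um; NA = full field.
#' @slot scanWindow half-width, um, of the window (about \code{windowCenter})
#'   inside which beams are propagated through the full phantom; outside it
#'   the sphere-free shifted reference is used (shift-invariant fill).
#'   NA disables the fill.
#' @slot windowCenter centre of the scan window, um.
#' @slot pivotHalfAngle mSPIM pivot half-range, degrees.
#' @slot pivotN number of pivot angles averaged.
#' @slot normalize logical; divide by the identical sphere-free run.
#' @slot boundaryFraction absorbing-boundary fraction passed to the engine.
#' @export
setClass("AcquisitionPlan",
    representation(mode = "character", beam = "BeamSpec",
                   detection = "DetectionSpec", zFocus = "numeric",
                   scanStep = "numeric", scanRange = "numeric",
                   scanWindow = "numeric", windowCenter = "numeric",
                   pivotHalfAngle = "numeric", pivotN = "integer",
                   normalize = "logical", boundaryFraction = "numeric"))

setValidity("AcquisitionPlan", function(object) {
    msg <- character()
    if (!object@mode %in% c("SPIM", "mSPIM", "DSLM", "mDSLM"))
        msg <- c(msg, "'mode' must be SPIM, mSPIM, DSLM or mDSLM")
    scanned <- object@mode %in% c("DSLM", "mDSLM")
    if (scanned && (!is.finite(object@scanStep) || object@scanStep <= 0))
        msg <- c(msg, "scanned modes need a positive 'scanStep'")
    if (!scanned && object@mode == "mSPIM" &&
        (object@pivotN < 1 || !is.finite(object@pivotHalfAngle)))
        msg <- c(msg, "mSPIM needs 'pivotN' >= 1 and a finite 'pivotHalfAngle'")
    if (length(msg)) msg else TRUE
})

#' Construct an AcquisitionPlan
#'
#' @param mode "SPIM", "mSPIM", "DSLM" or "mDSLM".
#' @param beam a [BeamSpec-class]. Defaults to the standard circular 0.06 beam
#'   for SPIM-family/DSLM and the 0.06/0.18 elliptical beam for mDSLM.
#' @param detection a [DetectionSpec-class]; widefield for SPIM/mSPIM,
#'   confocal-line for DSLM/mDSLM (set automatically if omitted).
#' @param zFocus focus depth, um.
#' @param scanStep scan increment, um.
#' @param scanRange length-2 y range, um (NA = full usable field).
#' @param scanWindow full-propagation window half-width, um (NA = propagate
#'   every position).
#' @param windowCenter window centre, um.
#' @param pivotHalfAngle mSPIM pivot half-range, degrees.
#' @param pivotN number of pivot angles.
#' @param normalize divide by the sphere-free reference run.
#' @param boundaryFraction absorbing-boundary fraction.
#' @return An [AcquisitionPlan-class] object.
#' @export
AcquisitionPlan <- function(mode, beam = NULL, detection = NULL, zFocus = 350,
                            scanStep = 0.25, scanRange = c(NA_real_, NA_real_),
                            scanWindow = NA_real_, windowCenter = 0,
                            pivotHalfAngle = 10, pivotN = 21L,
                            normalize = TRUE, boundaryFraction = 0.1) {
    if (is.null(beam))
        beam <- if (mode == "mDSLM") BeamSpec(0.06, 0.18) else BeamSpec(0.06)
    if (is.null(detection))
        detection <- DetectionSpec(
            mode = if (mode %in% c("SPIM", "mSPIM")) "widefield"
                   else "confocal-line")
    new("AcquisitionPlan", mode = mode, beam = beam, detection = detection,
        zFocus = as.numeric(zFocus), scanStep = as.numeric(scanStep),
        scanRange = as.numeric(scanRange), scanWindow = as.numeric(scanWindow),
        windowCenter = as.numeric(windowCenter),
        pivotHalfAngle = as.numeric(pivotHalfAngle),
        pivotN = as.integer(pivotN), normalize = as.logical(normalize),
        boundaryFraction = as.numeric(boundaryFraction))
}

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "BeamSpec", function(object) {
    cat(sprintf("BeamSpec: NA_x = %.3g, NA_y = %.3g, lambda = %.3g um, n = %.3g\n",
                object@naX, object@naY, object@wavelength, object@mediumIndex))
    cat(sprintf("  waists w0x = %.3g um, w0y = %s um; z_Rx = %.4g um\n",
                beamWaist(object@naX, object@wavelength),
                if (object@naY > 0)
                    sprintf("%.3g", beamWaist(object@naY, object@wavelength))
                else "Inf (collimated)",
                rayleighRange(object@naX, object@wavelength)))
})

setMethod("show", "GridSpec", function(object) {
    cat(sprintf("GridSpec: %d x %d x %d voxels (x, y, z) at %.3g x %.3g x %.3g um\n",
                object@nx, object@ny, object@nz, object@dx, object@dy, object@dz))
    cat(sprintf("  extent %.4g x %.4g x %.4g um\n",
                object@nx * object@dx, object@ny * object@dy,
                object@nz * object@dz))
})

setMethod("show", "SphereSpec", function(object) {
    cat(sprintf("SphereSpec: d = %.3g um, n = %.3g at (%.3g, %.3g, %.3g) um%s\n",
                object@diameter, object@index, object@center[1],
                object@center[2], object@center[3],
                if (object@fluorescent) " [fluorescent]" else ""))
})

setMethod("show", "Phantom", function(object) {
    cat(sprintf("Phantom: n_gel = %.3g, %d sphere(s), %s gel\n",
                object@nBackground, length(object@spheres),
                if (object@gelFluorescent) "fluorescent" else "non-fluorescent"))
    show(object@grid)
})

setMethod("show", "FieldSlice", function(object) {
    cat(sprintf("FieldSlice: %d x %d at z = %.4g um, power = %.6g\n",
                nrow(object@field), ncol(object@field), object@z,
                fieldPower(object)))
})

setMethod("show", "IntensityRecord", function(object) {
    kept <- c(if (length(object@axial)) "axial",
              if (length(object@planeYZ)) "planeYZ",
              if (length(object@camera)) "camera",
              if (length(object@power)) "power",
              if (length(object@radii)) "radii",
              if (length(object@focalPlane)) "focalPlane")
    cat(sprintf("IntensityRecord over %d slices; records: %s\n",
                object@grid@nz, paste(kept, collapse = ", ")))
})

setMethod("show", "DetectionSpec", function(object) {
    cat(sprintf("DetectionSpec: NA %.2g, lambda_em %.3g um, %s, PSF %s",
                object@na, object@lambdaEm, object@mode, object@psfModel))
    if (object@mode == "confocal-line")
        cat(sprintf(", slit %.3g um", object@slitWidth))
    cat("\n")
})

setMethod("show", "CameraImage", function(object) {
    cat(sprintf("CameraImage: %d x %d (y x z) at %.3g x %.3g um\n",
                nrow(object@image), ncol(object@image), object@dy, object@dz))
})

setMethod("show", "AcquiredStack", function(object) {
    cat(sprintf("AcquiredStack [%s]: %d x %d (y x z) at %.3g x %.3g um, %s\n",
                if (!is.null(object@provenance$mode)) object@provenance$mode
                else "?", nrow(object@image), ncol(object@image),
                object@dy, object@dz,
                if (object@normalized) "normalized" else "raw"))
})

setMethod("show", "AcquisitionPlan", function(object) {
    cat(sprintf("AcquisitionPlan: %s, z_focus = %.4g um, %s\n",
                object@mode, object@zFocus,
                if (object@normalize) "normalized" else "raw"))
    show(object@beam)
    show(object@detection)
})

## ---------------------------------------------------------------------------
## accessors
## ---------------------------------------------------------------------------

#' Accessors for simulation objects
#'
#' Small read-only accessors for the S4 containers; slots are implementation
#' detail and should be reached through these.
#'
#' @param x the object.
#' @return The corresponding field value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
naX <- function(x) x@naX

#' @rdname accessors
#' @export
naY <- function(x) x@naY

#' @rdname accessors
#' @export
wavelength <- function(x) x@wavelength

#' @rdname accessors
#' @export
mediumIndex <- function(x) x@mediumIndex

#' @rdname accessors
#' @export
stackImage <- function(x) x@image

#' @rdname accessors
#' @export
isNormalized <- function(x) x@normalized

#' @rdname accessors
#' @export
provenance <- function(x) x@provenance

#' @rdname accessors
#' @export
phantomGrid <- function(x) x@grid

#' @rdname accessors
#' @export
phantomSpheres <- function(x) x@spheres

#' @rdname accessors
#' @export
fieldMatrix <- function(x) x@field

#' Total transverse power of a field slice
#'
#' Sum of |u|^2 dx dy over the slice.
#'
#' @param field a [FieldSlice-class].
#' @return Numeric scalar.
#' @export
fieldPower <- function(field) {
    sum(Re(field@field)^2 + Im(field@field)^2) * field@dx * field@dy
}
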