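## Orchestration of the four light-sheet architectures, NA sweeps and
## z-tiling.

## snap a y position to the pixel grid (must already be a pixel multiple)
checkPixelMultiple <- function(val, pitch, what) {
    px <- val / pitch
    stopIfNot(all(abs(px - round(px)) < 1e-9),
              "%s must be a whole number of y pixels (dy = %g um)", what, pitch)
    round(px)
}

scanPositions <- function(plan, grid) {
    half <- grid@ny * grid@dy / 2
    usable <- half * (1 - 2 * plan@boundaryFraction)
    lo <- if (is.finite(plan@scanRange[1])) plan@scanRange[1] else
        -grid@dy * floor(usable / grid@dy)
    hi <- if (is.finite(plan@scanRange[2])) plan@scanRange[2] else
        grid@dy * floor(usable / grid@dy)
    stopIfNot(hi >= lo, "scan range is empty")
    ys <- seq(lo, hi, by = plan@scanStep)
    checkPixelMultiple(ys, grid@dy, "scan positions")
    ys
}

#' Run one light-sheet acquisition
#'
#' Simulates a full acquisition of one yz frame through a phantom:
#' \describe{
#'   \item{DSLM / mDSLM}{for each scan position a pencil beam displaced to
#'     y_s is propagated, the camera image formed, apertured by the confocal
#'     slit centred on the beam, and all positions summed. When the plan has
#'     a finite \code{scanWindow}, beams outside the window around
#'     \code{windowCenter} reuse the y-shifted sphere-free reference image
#'     (exact for beams that never feel the spheres).}
#'   \item{SPIM}{a single static flat-top sheet, widefield image.}
#'   \item{mSPIM}{unweighted incoherent average of widefield sheet images
#'     over the pivot angle set (the time-average of a pivoting sheet).}
#' }
#' With \code{normalize = TRUE} the summed image is divided element-wise by
#' the identical plan run on the sphere-free phantom.
#'
#' @param plan an [AcquisitionPlan-class].
#' @param phantom a [Phantom-class].
#' @return An [AcquiredStack-class] (yz image, rows = y, columns = z).
#' @examples
#' g  <- GridSpec(96, 96, 160, dx = 1.25)
#' ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 2, 50), 16)))
#' pl <- AcquisitionPlan("DSLM", zFocus = 140, scanStep = 5,
#'                       scanRange = c(-15, 15))
#' st <- runAcquisition(pl, ph)
#' @export
runAcquisition <- function(plan, phantom) {
    validObject(plan); validObject(phantom)
    grid <- phantom@grid
    det <- plan@detection
    if (plan@mode %in% c("DSLM", "mDSLM"))
        runScanned(plan, phantom)
    else
        runSheet(plan, phantom)
}

runScanned <- function(plan, phantom) {
    grid <- phantom@grid
    det <- plan@detection
    stopIfNot(det@mode == "confocal-line",
              "%s uses confocal-line detection", plan@mode)
    ys <- scanPositions(plan, grid)
    cfg <- function(y) PropagationConfig(plan@beam, plan@zFocus,
                                         boundaryFraction = plan@boundaryFraction,
                                         recordPlan = "camera",
                                         detection = det, sourceY = y)
    empty <- emptyPhantom(phantom)
    src0 <- makeSourceField(plan@beam, plan@zFocus, grid,
                            boundaryFraction = plan@boundaryFraction)
    refRec <- propagateBeam(src0, empty, cfg(0))
    refBase <- blurCameraAccumulator(refRec, det)

    haveSpheres <- length(phantom@spheres) > 0
    inWindow <- if (!is.finite(plan@scanWindow)) rep(TRUE, length(ys)) else
        abs(ys - plan@windowCenter) <= plan@scanWindow
    sumImg <- matrix(0, grid@ny, grid@nz)
    sumRef <- matrix(0, grid@ny, grid@nz)
    nProp <- 0L
    for (i in seq_along(ys)) {
        y <- ys[i]
        sPx <- checkPixelMultiple(y, grid@dy, "scan position")
        refImg <- rollRows(refBase, sPx)
        if (haveSpheres && inWindow[i]) {
            src <- if (sPx == 0) src0 else
                new("FieldSlice", field = rollCols(src0@field, sPx),
                    dx = src0@dx, dy = src0@dy, wavelength = src0@wavelength,
                    mediumIndex = src0@mediumIndex, z = 0)
            rec <- tryCatch(propagateBeam(src, phantom, cfg(y)),
                            error = function(e)
                stop(sprintf("propagation failed at scan position y = %g um: %s",
                             y, conditionMessage(e)), call. = FALSE))
            img <- blurCameraAccumulator(rec, det)
            nProp <- nProp + 1L
        } else {
            img <- refImg
        }
        mask <- slitMaskRows(grid, y, det@slitWidth)
        sumImg[mask, ] <- sumImg[mask, ] + img[mask, ]
        sumRef[mask, ] <- sumRef[mask, ] + refImg[mask, ]
    }
    finishStack(plan, grid, sumImg, sumRef,
                extra = list(scanPositions = ys, propagated = nProp))
}

slitMaskRows <- function(grid, beamY, slitWidth) {
    abs(yCoords(grid) - beamY) <= slitWidth / 2
}

runSheet <- function(plan, phantom) {
    grid <- phantom@grid
    det <- plan@detection
    stopIfNot(det@mode == "widefield",
              "%s uses widefield detection", plan@mode)
    angles <- if (plan@mode == "SPIM") 0 else
        if (plan@pivotN == 1L) 0 else
        seq(-plan@pivotHalfAngle, plan@pivotHalfAngle,
            length.out = plan@pivotN)
    empty <- emptyPhantom(phantom)
    sumImg <- matrix(0, grid@ny, grid@nz)
    sumRef <- matrix(0, grid@ny, grid@nz)
    for (th in angles) {
        src <- makeSourceField(plan@beam, plan@zFocus, grid,
                               sourceType = if (th == 0) "sheet"
                                            else "pivoted-sheet",
                               pivotAngle = th,
                               boundaryFraction = plan@boundaryFraction)
        cfgA <- PropagationConfig(plan@beam, plan@zFocus,
                                  boundaryFraction = plan@boundaryFraction,
                                  recordPlan = "camera", detection = det,
                                  sourceType = if (th == 0) "sheet"
                                               else "pivoted-sheet",
                                  pivotAngle = th)
        rec <- propagateBeam(src, phantom, cfgA)
        sumImg <- sumImg + blurCameraAccumulator(rec, det)
        refRec <- propagateBeam(src, empty, cfgA)
        sumRef <- sumRef + blurCameraAccumulator(refRec, det)
    }
    sumImg <- sumImg / length(angles)
    sumRef <- sumRef / length(angles)
    finishStack(plan, grid, sumImg, sumRef,
                extra = list(pivotAngles = angles))
}

finishStack <- function(plan, grid, sumImg, sumRef, extra = list()) {
    img <- if (plan@normalize) normalizedMap(sumImg, sumRef) else sumImg
    prov <- c(list(mode = plan@mode, zFocus = plan@zFocus,
                   normalize = plan@normalize, beam = plan@beam,
                   detection = plan@detection,
                   boundaryFraction = plan@boundaryFraction), extra)
    new("AcquiredStack", image = img, dy = grid@dy, dz = grid@dz,
        normalized = plan@normalize, provenance = prov)
}

#' Normalized single-beam focal intensity (static beam)
#'
#' Propagates one static pencil beam through the phantom and its sphere-free
#' reference and returns the normalized on-axis intensity at the focus
#' (mean over a small window of pixels around the focal on-axis position) —
#' the quantity reported for single-beam occlusion scenarios.
#'
#' @param beam a [BeamSpec-class] (\code{naY = 0} uses a sheet source).
#' @param phantom a [Phantom-class].
#' @param zFocus focus depth, um.
#' @param boundaryFraction absorbing-boundary fraction.
#' @param window focal window size in pixels per axis.
#' @return Normalized focal intensity (1 = unobstructed).
#' @export
singleBeamFocalRatio <- function(beam, phantom, zFocus,
                                 boundaryFraction = 0.1, window = 3) {
    grid <- phantom@grid
    srcType <- if (beam@naY > 0) "pencil" else "sheet"
    src <- makeSourceField(beam, zFocus, grid, sourceType = srcType,
                           boundaryFraction = boundaryFraction)
    cfgA <- PropagationConfig(beam, zFocus,
                              boundaryFraction = boundaryFraction,
                              recordPlan = "axial", sourceType = srcType)
    rec <- propagateBeam(src, phantom, cfgA)
    ref <- unobstructedReference(src, phantom, cfgA)
    focalIntensityRatio(rec, ref, window = window)
}

#' NA sweep over illumination apertures
#'
#' Evaluates one scalar metric on a grid of (NA_x, NA_y) pairs, reproducing
#' the illumination design trade-off maps:
#' \describe{
#'   \item{focus_intensity}{normalized single static beam focal intensity
#'     with the occluding sphere present.}
#'   \item{edge_signal}{relative confocal-slit signal at the field edges
#'     (z_focus +/- the in-medium Rayleigh range) in a sphere-free medium,
#'     scanned and slit-summed (1 means no roll-off).}
#' }
#' NA_y = 0 denotes a beam collimated in y (static-sheet limit). Cells whose
#' beams cannot be resolved on the grid are recorded as NA with the error
#' message, and the sweep continues.
#'
#' @param naXValues,naYValues numeric vectors of apertures.
#' @param phantom a [Phantom-class] (with the sphere for focus_intensity;
#'   spheres are dropped automatically for edge_signal).
#' @param zFocus focus depth, um.
#' @param metric "focus_intensity" or "edge_signal".
#' @param detection a [DetectionSpec-class] (edge_signal; default 20-um slit).
#' @param wavelength excitation wavelength, um.
#' @param mediumIndex background index.
#' @param scanStep,boundaryFraction see [AcquisitionPlan()].
#' @return A data.frame with columns naX, naY, value, status.
#' @export
runNASweep <- function(naXValues, naYValues, phantom, zFocus,
                       metric = c("focus_intensity", "edge_signal"),
                       detection = DetectionSpec(), wavelength = 0.660,
                       mediumIndex = 1.46, scanStep = 2,
                       boundaryFraction = 0.1) {
    metric <- match.arg(metric)
    cells <- expand.grid(naX = naXValues, naY = naYValues,
                         KEEP.OUT.ATTRS = FALSE)
    cells$value <- NA_real_
    cells$status <- "ok"
    for (i in seq_len(nrow(cells))) {
        beam <- BeamSpec(cells$naX[i], cells$naY[i], wavelength, mediumIndex)
        res <- tryCatch({
            if (metric == "focus_intensity")
                singleBeamFocalRatio(beam, phantom, zFocus,
                                     boundaryFraction = boundaryFraction)
            else
                1 - scannedEdgeRolloff(beam, emptyPhantom(phantom), zFocus,
                                       detection = detection,
                                       scanStep = scanStep,
                                       boundaryFraction = boundaryFraction)
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) cells$status[i] <- res
        else cells$value[i] <- res
    }
    cells
}

#' Field-edge roll-off of a scanned confocal acquisition
#'
#' Simulates the sphere-free scanned, slit-apertured acquisition (exploiting
#' y shift-invariance: one propagation, shifted for every scan position) and
#' returns \code{1 - mean(edge signal) / focus signal}, where the signal is
#' read on the summed image at y = 0 and the field edges sit at
#' \code{zFocus +/- n * z_R,x} — the depth at which the propagating sheet has
#' physically expanded by sqrt(2) in the medium of index n.
#'
#' @param beam a [BeamSpec-class].
#' @param phantom a (sphere-free) [Phantom-class]; spheres are dropped.
#' @param zFocus focus depth, um.
#' @param detection a confocal-line [DetectionSpec-class].
#' @param scanStep scan increment, um.
#' @param boundaryFraction absorbing-boundary fraction.
#' @param window readout window, pixels.
#' @return The roll-off as a fraction (0 = flat field).
#' @export
scannedEdgeRolloff <- function(beam, phantom, zFocus,
                               detection = DetectionSpec(), scanStep = 2,
                               boundaryFraction = 0.1, window = 3) {
    stack <- scannedReferenceStack(beam, phantom, zFocus, detection,
                                   scanStep, boundaryFraction)
    edgeRolloff(stack, beam, zFocus, window = window)
}

## sphere-free scanned confocal stack via shift invariance (raw, not
## normalized: the scenario has no occluder)
scannedReferenceStack <- function(beam, phantom, zFocus, detection, scanStep,
                                  boundaryFraction) {
    grid <- phantom@grid
    srcType <- if (beam@naY > 0) "pencil" else "sheet"
    src <- makeSourceField(beam, zFocus, grid, sourceType = srcType,
                           boundaryFraction = boundaryFraction)
    cfgA <- PropagationConfig(beam, zFocus,
                              boundaryFraction = boundaryFraction,
                              recordPlan = "camera", detection = detection,
                              sourceType = srcType)
    rec <- propagateBeam(src, emptyPhantom(phantom), cfgA)
    base <- blurCameraAccumulator(rec, detection)
    half <- grid@ny * grid@dy / 2 * (1 - 2 * boundaryFraction)
    ys <- seq(-grid@dy * floor(half / grid@dy),
              grid@dy * floor(half / grid@dy), by = scanStep)
    sumImg <- matrix(0, grid@ny, grid@nz)
    for (y in ys) {
        sPx <- checkPixelMultiple(y, grid@dy, "scan position")
        img <- rollRows(base, sPx)
        mask <- slitMaskRows(grid, y, detection@slitWidth)
        sumImg[mask, ] <- sumImg[mask, ] + img[mask, ]
    }
    new("AcquiredStack", image = sumImg, dy = grid@dy, dz = grid@dz,
        normalized = FALSE,
        provenance = list(mode = "scanned-reference", zFocus = zFocus,
                          beam = beam, detection = detection,
                          boundaryFraction = boundaryFraction,
                          scanPositions = ys))
}

#' Tiled acquisition along the propagation axis
#'
#' Repeats an acquisition with the beam focus advanced in steps of
#' \code{tileStep}, keeping from each tile the axial band
#' \code{|z - z_focus| <= tileStep / 2} and concatenating the bands into one
#' stack — the in-silico analogue of axial tiling during deep imaging.
#'
#' @param plan an [AcquisitionPlan-class] (its \code{zFocus} is ignored).
#' @param phantom a [Phantom-class].
#' @param tileStep tile advance, um.
#' @param tileCenters focus depths of the tiles, um; defaults to covering
#'   the grid depth in \code{tileStep} steps.
#' @return An [AcquiredStack-class] whose provenance lists tile boundaries.
#' @export
runTiledZ <- function(plan, phantom, tileStep = 50, tileCenters = NULL) {
    stopIfNot(tileStep > 0, "tileStep must be positive")
    grid <- phantom@grid
    zExt <- grid@nz * grid@dz
    if (is.null(tileCenters))
        tileCenters <- seq(tileStep / 2, zExt - tileStep / 2 + 1e-9,
                           by = tileStep)
    stopIfNot(all(tileCenters > 0 & tileCenters < zExt),
              "tile centres must lie within the grid depth (0, %g)", zExt)
    zc <- zCoords(grid)
    img <- matrix(NA_real_, grid@ny, grid@nz)
    prov <- NULL
    for (ti in seq_along(tileCenters)) {
        zf <- tileCenters[ti]
        tilePlan <- plan
        tilePlan@zFocus <- zf
        st <- runAcquisition(tilePlan, phantom)
        lo <- zf - tileStep / 2
        hi <- zf + tileStep / 2
        cols <- if (ti == 1) which(zc <= hi)
                else if (ti == length(tileCenters)) which(zc > lo)
                else which(zc > lo & zc <= hi)
        img[, cols] <- st@image[, cols]
        if (is.null(prov)) prov <- st@provenance
    }
    filled <- !is.na(img[1, ])
    img <- img[, filled, drop = FALSE]
    prov$tileCenters <- tileCenters
    prov$tileStep <- tileStep
    prov$zKept <- zc[filled]
    new("AcquiredStack", image = img, dy = grid@dy, dz = grid@dz,
        normalized = plan@normalize, provenance = prov)
}
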