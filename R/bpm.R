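## Split-step (angular-spectrum + thin phase screen) scalar beam propagation.
##
## Fields are propagated with the carrier wavenumber k = 2*pi*n_bg/lambda;
## phase screens apply the index contrast relative to the background via the
## vacuum wavenumber k0 = 2*pi/lambda. The evanescent band of the angular
## spectrum is hard-truncated. Each step applies diffraction over dz, then the
## phase screen sampled at the slice centre, then the absorbing boundary.

## transfer-function phase kz(kx, ky), with evanescent components zeroed
axialWavenumbers <- function(nx, ny, dx, dy, k) {
    kx <- 2 * pi * fftFreq(nx, dx)
    ky <- 2 * pi * fftFreq(ny, dy)
    arg <- outer(k^2 - kx^2, ky^2, "-")
    kz <- sqrt(pmax(arg, 0))
    list(kz = kz, prop = arg > 0)
}

## super-Gaussian absorbing boundary, separable amplitude mask
boundaryMask <- function(nx, ny, fraction) {
    edge <- function(n) {
        if (fraction <= 0) return(rep(1, n))
        w <- max(1L, round(fraction * n))
        m <- rep(1, n)
        t <- seq_len(w) / w
        prof <- exp(-6 * t^4)
        m[w:1] <- prof
        m[(n - w + 1):n] <- prof
        m
    }
    outer(edge(nx), edge(ny))
}

## angular sampling check: the beam's transverse bandwidth (k0 * NA) must sit
## below the grid Nyquist frequency with some headroom
checkResolvable <- function(beam, dx, dy) {
    lim <- function(na, pitch, axis) {
        if (na <= 0) return(invisible())
        stopIfNot(pitch <= beam@wavelength / (2 * na) * 0.999999,
                  paste0("source under-resolved in %s: pitch %g um exceeds ",
                         "lambda/(2 NA) = %g um for NA = %g"),
                  axis, pitch, beam@wavelength / (2 * na), na)
    }
    lim(beam@naX, dx, "x")
    lim(beam@naY, dy, "y")
}

#' Construct the source field at the entry face
#'
#' Builds the scalar field u(x, y) at z = 0 for a beam whose x- and y-waists
#' (waist radius \eqn{\lambda/(\pi NA)} per axis) are co-located at
#' \code{zFocus}: the analytic waist field is defined on the grid and
#' back-propagated to z = 0 through the homogeneous background medium by the
#' same angular-spectrum operator used for forward stepping, so no explicit
#' astigmatic phase formula is needed. Sheet sources are flat-top in y
#' (collimated) with Gaussian focusing in x only; pivoted sheets are tilted
#' in the yz plane about the focal point. Power is normalized to 1.
#'
#' @param beam a [BeamSpec-class].
#' @param zFocus focus depth, um (within the grid).
#' @param grid a [GridSpec-class].
#' @param sourceType "pencil", "sheet" or "pivoted-sheet".
#' @param sourceY beam-axis displacement along y, um (must be a whole number
#'   of y pixels).
#' @param pivotAngle tilt of a pivoted sheet, degrees.
#' @param fieldWidthY flat-top width of sheet sources, um (NA = field width
#'   minus the absorbing margin); edges are softened over 5 um.
#' @param boundaryFraction absorbing-boundary fraction (used for the sheet
#'   default width).
#' @return A [FieldSlice-class] at z = 0 with unit power.
#' @examples
#' g <- GridSpec(128, 128, 200, dx = 1)
#' f <- makeSourceField(BeamSpec(0.06), zFocus = 100, grid = g)
#' fieldPower(f)
#' @export
makeSourceField <- function(beam, zFocus, grid, sourceType = "pencil",
                            sourceY = 0, pivotAngle = 0,
                            fieldWidthY = NA_real_, boundaryFraction = 0.1) {
    validObject(beam); validObject(grid)
    stopIfNot(zFocus >= 0 && zFocus <= grid@nz * grid@dz,
              "makeSourceField: zFocus = %g um outside the grid [0, %g]",
              zFocus, grid@nz * grid@dz)
    checkResolvable(beam, grid@dx, grid@dy)
    xs <- xCoords(grid); ys <- yCoords(grid)
    k <- 2 * pi * beam@mediumIndex / beam@wavelength
    w0x <- beamWaist(beam@naX, beam@wavelength)
    ax <- exp(-xs^2 / w0x^2)

    if (sourceType == "pencil") {
        stopIfNot(beam@naY > 0, "pencil source requires naY > 0")
        w0y <- beamWaist(beam@naY, beam@wavelength)
        u <- outer(ax, exp(-ys^2 / w0y^2)) + 0i
        u <- backPropagate(u, grid, k, zFocus)
    } else {
        ## sheet: focused in x only, flat-top collimated in y
        if (is.na(fieldWidthY))
            fieldWidthY <- grid@ny * grid@dy * (1 - 2 * boundaryFraction)
        ay <- flatTop(ys, fieldWidthY, edge = 5)
        Ux <- stats::fft(ax + 0i)
        kx <- 2 * pi * fftFreq(grid@nx, grid@dx)
        argx <- k^2 - kx^2
        kzx <- sqrt(pmax(argx, 0))
        Ux <- Ux * exp(-1i * kzx * zFocus) * (argx > 0)
        ux <- stats::fft(Ux, inverse = TRUE) / grid@nx
        u <- outer(ux, ay + 0i)
        if (sourceType == "pivoted-sheet" && pivotAngle != 0) {
            th <- pivotAngle * pi / 180
            shiftPx <- round(-zFocus * tan(th) / grid@dy)
            u <- rollCols(u, shiftPx)
            tilt <- exp(1i * k * sin(th) * ys)
            u <- sweep(u, 2, tilt, "*")
        } else if (sourceType != "sheet" && sourceType != "pivoted-sheet") {
            stop("unknown sourceType: ", sourceType, call. = FALSE)
        }
    }

    if (sourceY != 0) {
        sPx <- sourceY / grid@dy
        stopIfNot(abs(sPx - round(sPx)) < 1e-9,
                  "sourceY = %g um is not a whole number of y pixels (dy = %g)",
                  sourceY, grid@dy)
        u <- rollCols(u, round(sPx))
    }
    p <- sum(Re(u)^2 + Im(u)^2) * grid@dx * grid@dy
    u <- u / sqrt(p)
    new("FieldSlice", field = u, dx = grid@dx, dy = grid@dy,
        wavelength = beam@wavelength, mediumIndex = beam@mediumIndex, z = 0)
}

backPropagate <- function(u, grid, k, distance) {
    wn <- axialWavenumbers(grid@nx, grid@ny, grid@dx, grid@dy, k)
    U <- stats::fft(u) * exp(-1i * wn$kz * distance) * wn$prop
    stats::fft(U, inverse = TRUE) / length(U)
}

flatTop <- function(ys, width, edge = 5) {
    half <- width / 2
    a <- numeric(length(ys))
    inside <- abs(ys) <= half - edge
    a[inside] <- 1
    ramp <- abs(ys) > half - edge & abs(ys) <= half
    a[ramp] <- 0.5 * (1 + cos(pi * (abs(ys[ramp]) - (half - edge)) / edge))
    a
}

## axial detection weights for the camera accumulator (gaussian-approx model)
gaussianAxialWeights <- function(det, grid) {
    sigAx <- det@axC * det@mediumIndex * det@lambdaEm / det@na^2
    w <- stats::dnorm(xCoords(grid), 0, sigAx)
    w / sum(w)
}

## defocus bins for the scalar-defocus model: flat axial response over
## |x| <= xMax (laterally energy-conserving widefield kernel slices)
scalarDefocusBins <- function(det, grid, nBins = 9) {
    xMax <- 4 * det@mediumIndex * det@lambdaEm / det@na^2
    xs <- xCoords(grid)
    keep <- which(abs(xs) <= xMax)
    edges <- seq(-xMax, xMax, length.out = nBins + 1)
    idx <- findInterval(xs[keep], edges, all.inside = TRUE)
    list(rows = keep, bin = idx, nBins = nBins,
         centers = (edges[-1] + edges[-(nBins + 1)]) / 2,
         weight = 1 / length(keep))
}

#' Propagate a field through a phantom
#'
#' Advances the field slice by slice through the phantom: angular-spectrum
#' diffraction over dz in the background medium, a thin phase screen
#' \eqn{\exp(i k_0 (n - n_{bg}) dz)} where a slice intersects spheres, and
#' the absorbing boundary, recording the requested per-slice quantities.
#'
#' @param field a [FieldSlice-class] at z = 0 (see [makeSourceField()]).
#' @param phantom a [Phantom-class] on the same transverse grid.
#' @param config a [PropagationConfig-class]; \code{config@dz} must be NA or
#'   equal to the grid's dz (the phantom voxelization sets the step).
#' @return An [IntensityRecord-class].
#' @examples
#' g  <- GridSpec(96, 96, 150, dx = 1)
#' ph <- buildPhantom(g)
#' f  <- makeSourceField(BeamSpec(0.06), 75, g)
#' rec <- propagateBeam(f, ph, PropagationConfig(BeamSpec(0.06), 75,
#'                      recordPlan = c("axial", "power")))
#' @export
propagateBeam <- function(field, phantom, config) {
    validObject(field); validObject(phantom); validObject(config)
    grid <- phantom@grid
    stopIfNot(nrow(field@field) == grid@nx && ncol(field@field) == grid@ny,
              "field (%d x %d) does not match phantom grid (%d x %d)",
              nrow(field@field), ncol(field@field), grid@nx, grid@ny)
    stopIfNot(abs(field@dx - grid@dx) < 1e-12 && abs(field@dy - grid@dy) < 1e-12,
              "field pitch does not match phantom grid pitch")
    if (!is.na(config@dz))
        stopIfNot(abs(config@dz - grid@dz) < 1e-12,
                  "config dz = %g must equal the grid dz = %g (refine the grid to refine the step)",
                  config@dz, grid@dz)
    dz <- grid@dz
    nz <- grid@nz
    k <- 2 * pi * field@mediumIndex / field@wavelength
    k0 <- 2 * pi / field@wavelength
    wn <- axialWavenumbers(grid@nx, grid@ny, grid@dx, grid@dy, k)
    H <- exp(1i * wn$kz * dz) * wn$prop
    ## first step advances dz/2 so records and phase screens sit at slice
    ## centres (k - 1/2) dz
    Hhalf <- exp(1i * wn$kz * (dz / 2)) * wn$prop
    M <- boundaryMask(grid@nx, grid@ny, config@boundaryFraction)
    invN <- 1 / (grid@nx * grid@ny)
    dA <- grid@dx * grid@dy

    plan <- config@recordPlan
    wantAxial <- "axial" %in% plan
    wantYZ <- "planeYZ" %in% plan
    wantCam <- "camera" %in% plan
    wantPow <- "power" %in% plan
    wantRad <- "radii" %in% plan
    wantFoc <- "focalPlane" %in% plan

    cx <- nearestIndices(xCoords(grid), 0, 4)
    cy <- nearestIndices(yCoords(grid), 0, 4)
    midx <- nearestIndices(xCoords(grid), 0, 2)
    izFocus <- max(1L, min(nz, round(config@zFocus / dz + 0.5)))

    axial <- if (wantAxial) array(0, c(length(cx), length(cy), nz)) else array(0, c(0, 0, 0))
    planeYZ <- if (wantYZ) matrix(0, grid@ny, nz) else matrix(0, 0, 0)
    camera <- if (wantCam) matrix(0, grid@ny, nz) else matrix(0, 0, 0)
    power <- if (wantPow) numeric(nz) else numeric(0)
    radii <- if (wantRad) matrix(NA_real_, nz, 2,
                                 dimnames = list(NULL, c("wx", "wy"))) else matrix(0, 0, 0)
    focalPlane <- matrix(0, 0, 0)

    camBins <- NULL
    scalarPSF <- wantCam && !is.null(config@detection) &&
        config@detection@psfModel == "scalar-defocus"
    if (wantCam) {
        if (scalarPSF) {
            camBins <- scalarDefocusBins(config@detection, grid)
            binAcc <- lapply(seq_len(camBins$nBins),
                             function(i) matrix(0, grid@ny, nz))
        } else {
            wAx <- gaussianAxialWeights(config@detection, grid)
        }
    }

    xs <- xCoords(grid); ys <- yCoords(grid)
    u <- field@field

    for (iz in seq_len(nz)) {
        U <- stats::fft(u)
        u <- stats::fft(U * (if (iz == 1L) Hhalf else H), inverse = TRUE) *
            invN
        ns <- refractiveSlice(phantom, iz)
        if (!is.null(ns))
            u <- u * exp((1i * k0 * dz) * (ns - phantom@nBackground))
        u <- u * M
        I <- Re(u)^2 + Im(u)^2

        if (wantPow) power[iz] <- sum(I) * dA
        if (wantAxial) axial[, , iz] <- I[cx, cy]
        if (wantYZ) planeYZ[, iz] <- colMeans(I[midx, , drop = FALSE])
        if (wantCam) {
            fs <- fluorSlice(phantom, iz)
            IF <- if (is.null(fs)) {
                fBg <- if (phantom@gelFluorescent) 1 else phantom@fluorBackground
                if (fBg == 1) I else I * fBg
            } else I * fs
            if (scalarPSF) {
                sub <- IF[camBins$rows, , drop = FALSE] * camBins$weight
                for (b in seq_len(camBins$nBins)) {
                    rows <- camBins$bin == b
                    if (any(rows))
                        binAcc[[b]][, iz] <- colSums(sub[rows, , drop = FALSE])
                }
            } else {
                camera[, iz] <- colSums(IF * wAx)
            }
        }
        if (wantRad) {
            tot <- sum(I)
            if (tot > 0) {
                px <- rowSums(I); py <- colSums(I)
                mx <- sum(px * xs) / tot; my <- sum(py * ys) / tot
                radii[iz, 1] <- 2 * sqrt(sum(px * (xs - mx)^2) / tot)
                radii[iz, 2] <- 2 * sqrt(sum(py * (ys - my)^2) / tot)
            }
        }
        if (wantFoc && iz == izFocus) focalPlane <- I
        if (iz %% 64L == 0L && !is.finite(sum(Re(u[1, ]))))
            stop(sprintf("propagateBeam: non-finite field at slice %d (z = %g um)",
                         iz, iz * dz), call. = FALSE)
    }
    if (scalarPSF) camera <- Reduce(`+`, binAcc)

    new("IntensityRecord", grid = grid, axial = axial, planeYZ = planeYZ,
        camera = camera, power = power, radii = radii,
        focalPlane = focalPlane,
        meta = list(zFocus = config@zFocus, sourceY = config@sourceY,
                    beam = config@beam, dz = dz,
                    detection = config@detection,
                    cameraBins = if (scalarPSF) binAcc else NULL,
                    binCenters = if (scalarPSF) camBins$centers else NULL,
                    boundaryFraction = config@boundaryFraction,
                    nBackground = phantom@nBackground))
}

#' Sphere-free reference run
#'
#' Repeats a propagation with all spheres removed from the phantom; used as
#' the element-wise denominator for normalized intensity and image maps.
#'
#' @param field the source [FieldSlice-class] (same as the obstructed run).
#' @param phantom the [Phantom-class] whose spheres are dropped.
#' @param config the [PropagationConfig-class] of the obstructed run.
#' @return An [IntensityRecord-class] of the homogeneous-medium run.
#' @export
unobstructedReference <- function(field, phantom, config) {
    propagateBeam(field, emptyPhantom(phantom), config)
}

#' Drop all spheres from a phantom
#'
#' @param phantom a [Phantom-class].
#' @return The same phantom with an empty sphere list.
#' @export
emptyPhantom <- function(phantom) {
    buildPhantom(phantom@grid, phantom@nBackground, list(),
                 gelFluorescent = phantom@gelFluorescent,
                 fluorBackground = phantom@fluorBackground)
}

#' Element-wise normalized map
#'
#' Divides an obstructed-run map by its sphere-free reference with a small
#' epsilon guard (relative to the reference maximum) against empty pixels.
#'
#' @param x numeric array/matrix (obstructed run).
#' @param ref numeric array/matrix of identical shape (reference run).
#' @param eps relative epsilon guard.
#' @return Array of normalized values.
#' @export
normalizedMap <- function(x, ref, eps = 1e-12) {
    stopIfNot(identical(dim(x), dim(ref)) && length(x) == length(ref),
              "normalizedMap: shapes differ")
    guard <- eps * max(ref)
    x / pmax(ref, guard)
}

## fit 1/e^2 radii from a recorded "radii" track (already moment-based)
recordRadii <- function(rec) {
    stopIfNot(length(rec@radii) > 0,
              "record has no 'radii' track; add \"radii\" to the record plan")
    rec@radii
}
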