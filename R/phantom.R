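## Sphere-in-gel phantom construction and lazy voxelization.

sphereRadius <- function(s) s@diameter / 2

## bounds check: sphere fully inside the grid volume
sphereInBounds <- function(s, grid) {
    r <- sphereRadius(s)
    xr <- range(xCoords(grid)) + c(-grid@dx, grid@dx) / 2
    yr <- range(yCoords(grid)) + c(-grid@dy, grid@dy) / 2
    s@center[1] - r >= xr[1] && s@center[1] + r <= xr[2] &&
    s@center[2] - r >= yr[1] && s@center[2] + r <= yr[2] &&
    s@center[3] - r >= 0 && s@center[3] + r <= grid@nz * grid@dz
}

#' Build a sphere-in-gel phantom
#'
#' Assembles a [Phantom-class]: a uniform gel of index \code{nBackground}
#' containing the given spheres. Voxelization is lazy and deterministic: a
#' voxel belongs to a sphere iff its centre lies inside it (hard boundary),
#' with overlap ties resolved to the nearest sphere centre (earlier spheres
#' win exact ties).
#'
#' @param grid a [GridSpec-class].
#' @param nBackground gel refractive index (default 1.46, an index-matched
#'   TDE-cleared agarose gel).
#' @param spheres list of [SphereSpec-class] (may be empty).
#' @param gelFluorescent logical; TRUE for a dyed gel (F = 1 outside spheres,
#'   0 inside non-fluorescent spheres), FALSE for fluorescent-sphere phantoms
#'   (F = 1 inside fluorescent spheres, \code{fluorBackground} outside).
#' @param fluorBackground gel fluorophore level for non-fluorescent gels
#'   (dye bleed-through; ~0.1 in bead-in-scattering-gel experiments).
#' @param allowOverlap permit overlapping spheres.
#' @return A [Phantom-class].
#' @examples
#' g  <- GridSpec(60, 60, 120, dx = 1)
#' ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 2, 60), 20)))
#' @export
buildPhantom <- function(grid, nBackground = 1.46, spheres = list(),
                         gelFluorescent = TRUE, fluorBackground = 0,
                         allowOverlap = FALSE) {
    validObject(grid)
    if (is(spheres, "SphereSpec")) spheres <- list(spheres)
    for (s in spheres) {
        validObject(s)
        stopIfNot(sphereInBounds(s, grid),
                  "buildPhantom: sphere at (%g, %g, %g) um (d = %g) exceeds grid bounds",
                  s@center[1], s@center[2], s@center[3], s@diameter)
    }
    if (!allowOverlap && length(spheres) > 1) {
        for (i in seq_along(spheres)[-1]) for (j in seq_len(i - 1)) {
            dc <- sqrt(sum((spheres[[i]]@center - spheres[[j]]@center)^2))
            stopIfNot(dc >= sphereRadius(spheres[[i]]) + sphereRadius(spheres[[j]]),
                      "buildPhantom: spheres %d and %d overlap (set allowOverlap = TRUE to permit)",
                      j, i)
        }
    }
    new("Phantom", grid = grid, nBackground = as.numeric(nBackground),
        spheres = spheres, gelFluorescent = as.logical(gelFluorescent),
        fluorBackground = as.numeric(fluorBackground), seed = NA_integer_)
}

## spheres whose shell intersects slice at height z
spheresAtZ <- function(phantom, z) {
    Filter(function(s) abs(z - s@center[3]) < sphereRadius(s),
           phantom@spheres)
}

## For one z slice, a list(inside = logical matrix or NULL, index = matrix)
sliceMembership <- function(phantom, iz) {
    grid <- phantom@grid
    z <- (iz - 0.5) * grid@dz
    act <- spheresAtZ(phantom, z)
    if (!length(act)) return(NULL)
    xs <- xCoords(grid); ys <- yCoords(grid)
    best <- NULL           # squared distance to owning sphere centre
    owner <- NULL          # integer matrix of sphere ids (0 = gel)
    for (k in seq_along(act)) {
        s <- act[[k]]
        rz2 <- sphereRadius(s)^2 - (z - s@center[3])^2
        dx2 <- (xs - s@center[1])^2
        dy2 <- (ys - s@center[2])^2
        d2 <- outer(dx2, dy2, "+")
        inside <- d2 < rz2
        if (!any(inside)) next
        d2tot <- d2 + (z - s@center[3])^2
        if (is.null(owner)) {
            owner <- matrix(0L, grid@nx, grid@ny)
            best <- matrix(Inf, grid@nx, grid@ny)
        }
        take <- inside & (d2tot < best)
        owner[take] <- k
        best[take] <- d2tot[take]
    }
    if (is.null(owner) || !any(owner > 0L)) return(NULL)
    list(owner = owner, spheres = act)
}

#' Refractive-index and fluorophore slices
#'
#' Evaluate one transverse (x, y) slice of the voxelized refractive index
#' n(x, y, z) or fluorophore map F(x, y, z) at slice \code{iz}. Returns NULL
#' when the slice is pure background (uniform \code{nBackground}, uniform
#' background fluorophore) so propagation loops can skip work.
#'
#' @param phantom a [Phantom-class].
#' @param iz slice index, 1..nz.
#' @return An nx x ny matrix, or NULL for uniform background slices.
#' @export
refractiveSlice <- function(phantom, iz) {
    mem <- sliceMembership(phantom, iz)
    if (is.null(mem)) return(NULL)
    n <- matrix(phantom@nBackground, phantom@grid@nx, phantom@grid@ny)
    for (k in seq_along(mem$spheres))
        n[mem$owner == k] <- mem$spheres[[k]]@index
    n
}

#' @rdname refractiveSlice
#' @export
fluorSlice <- function(phantom, iz) {
    fBg <- if (phantom@gelFluorescent) 1 else phantom@fluorBackground
    mem <- sliceMembership(phantom, iz)
    if (is.null(mem)) return(NULL)
    f <- matrix(fBg, phantom@grid@nx, phantom@grid@ny)
    for (k in seq_along(mem$spheres))
        f[mem$owner == k] <- if (mem$spheres[[k]]@fluorescent) 1 else 0
    f
}

#' Materialize phantom volumes
#'
#' Builds the full 3D refractive-index or fluorophore array. Intended for
#' small grids (inspection, export, convergence tests); refuses volumes over
#' 5e7 voxels — use the slice accessors for full-scale runs.
#'
#' @param phantom a [Phantom-class].
#' @return A numeric nx x ny x nz array.
#' @export
refractiveVolume <- function(phantom) {
    materializeVolume(phantom, refractiveSlice, phantom@nBackground)
}

#' @rdname refractiveVolume
#' @export
fluorVolume <- function(phantom) {
    fBg <- if (phantom@gelFluorescent) 1 else phantom@fluorBackground
    materializeVolume(phantom, fluorSlice, fBg)
}

materializeVolume <- function(phantom, sliceFun, fill) {
    grid <- phantom@grid
    nvox <- as.double(grid@nx) * grid@ny * grid@nz
    stopIfNot(nvox <= 5e7,
              "volume of %.3g voxels too large to materialize; use the slice accessors",
              nvox)
    vol <- array(fill, c(grid@nx, grid@ny, grid@nz))
    for (iz in seq_len(grid@nz)) {
        s <- sliceFun(phantom, iz)
        if (!is.null(s)) vol[, , iz] <- s
    }
    vol
}

#' Random small-sphere phantom
#'
#' Draws non-overlapping sphere centres uniformly in the grid volume by
#' rejection sampling until the requested sphere volume fraction is reached,
#' emulating a bead-loaded gel. Deterministic for a given seed (the caller's
#' RNG state is left untouched).
#'
#' @param grid a [GridSpec-class].
#' @param diameter sphere diameter, um (default 6, the small-bead phantom).
#' @param volumeFraction target sphere volume fraction (< 0.1 so rejection
#'   sampling terminates).
#' @param seed integer seed.
#' @param minGap minimum surface-to-surface gap between spheres, um.
#' @param nBackground gel index.
#' @param index sphere index.
#' @param maxAttempts rejection-sampling budget per sphere.
#' @param edgeMargin extra clearance from the transverse grid edges, um
#'   (keeps spheres out of the absorbing boundary).
#' @return A [Phantom-class] with \code{gelFluorescent = TRUE}.
#' @examples
#' g  <- GridSpec(80, 80, 150, dx = 1)
#' ph <- randomSpherePhantom(g, volumeFraction = 0.002, seed = 1)
#' length(phantomSpheres(ph))
#' @export
randomSpherePhantom <- function(grid, diameter = 6, volumeFraction = 0.002,
                                seed = 1L, minGap = 0, nBackground = 1.46,
                                index = 1.59, maxAttempts = 2000L,
                                edgeMargin = 0) {
    validObject(grid)
    stopIfNot(volumeFraction >= 0 && volumeFraction < 0.1,
              "randomSpherePhantom: 'volumeFraction' must lie in [0, 0.1)")
    r <- diameter / 2
    vol <- (grid@nx * grid@dx) * (grid@ny * grid@dy) * (grid@nz * grid@dz)
    vSphere <- 4 / 3 * pi * r^3
    nTarget <- round(volumeFraction * vol / vSphere)
    if (nTarget == 0)
        return(buildPhantom(grid, nBackground))
    xr <- range(xCoords(grid)) + c(r + edgeMargin, -r - edgeMargin)
    yr <- range(yCoords(grid)) + c(r + edgeMargin, -r - edgeMargin)
    zr <- c(r, grid@nz * grid@dz - r)
    stopIfNot(xr[1] < xr[2] && yr[1] < yr[2] && zr[1] < zr[2],
              "randomSpherePhantom: grid too small for spheres of diameter %g um",
              diameter)
    centers <- withSeed(seed, {
        acc <- matrix(NA_real_, nTarget, 3)
        placed <- 0L
        attempts <- 0L
        dmin <- diameter + minGap
        while (placed < nTarget && attempts < maxAttempts * nTarget) {
            attempts <- attempts + 1L
            cand <- c(stats::runif(1, xr[1], xr[2]),
                      stats::runif(1, yr[1], yr[2]),
                      stats::runif(1, zr[1], zr[2]))
            if (placed > 0L) {
                d2 <- colSums((t(acc[seq_len(placed), , drop = FALSE]) - cand)^2)
                if (any(d2 < dmin^2)) next
            }
            placed <- placed + 1L
            acc[placed, ] <- cand
        }
        if (placed < nTarget)
            stop(sprintf(paste0(
                "randomSpherePhantom: packing infeasible; placed %d of %d ",
                "spheres (achieved fraction %.3g of requested %.3g)"),
                placed, nTarget, placed * vSphere / vol, volumeFraction),
                call. = FALSE)
        acc
    })
    spheres <- lapply(seq_len(nTarget), function(i)
        SphereSpec(centers[i, ], diameter = diameter, index = index))
    ph <- buildPhantom(grid, nBackground, spheres,
                       allowOverlap = minGap <= 0)
    ph@seed <- as.integer(seed)
    ph
}

#' Voxelized sphere volume
#'
#' Total volume (um^3) of voxels assigned to spheres — a convergence
#' diagnostic against the analytic 4/3 pi r^3.
#'
#' @param phantom a [Phantom-class].
#' @return Numeric scalar, um^3.
#' @export
voxelizedSphereVolume <- function(phantom) {
    grid <- phantom@grid
    vvox <- grid@dx * grid@dy * grid@dz
    total <- 0
    for (iz in seq_len(grid@nz)) {
        mem <- sliceMembership(phantom, iz)
        if (!is.null(mem)) total <- total + sum(mem$owner > 0L) * vvox
    }
    total
}
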