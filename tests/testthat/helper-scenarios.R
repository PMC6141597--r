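# Shared small-scale scenario helpers. Heavy simulation results are cached
# per test run so several tests can reuse one propagation.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
    if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
    get(key, envir = .cache)
}

# fast grid for unit-scale propagation checks (not the occlusion scenario)
tinyGrid <- function(nz = 160, dx = 1.25, nx = 96)
    GridSpec(nx, nx, nz, dx = dx, dy = dx, dz = 1.25)

# the coarse-preset occlusion scenario used by the acceptance-criteria tests
coarseOcclusionRatio <- function(beamName) {
    cached(paste0("occl_", beamName), {
        beam <- if (beamName == "dslm") dslmBeam() else mdslmBeam()
        occlusionFocalRatio(beam, preset = presetGrid("coarse", 370))
    })
}

coarseScannedRatio <- function(beamName) {
    cached(paste0("scan_", beamName), {
        beam <- if (beamName == "dslm") dslmBeam() else mdslmBeam()
        occlusionScannedRatio(beam, preset = presetGrid("coarse", 370),
                              scanStep = 2, window = 30)
    })
}

coarseEdgeRolloff <- function(beamName) {
    cached(paste0("edge_", beamName), {
        beam <- if (beamName == "dslm") dslmBeam() else mdslmBeam()
        fieldEdgeRolloff(beam, preset = presetGrid("coarse", 450),
                         scanStep = 2)
    })
}

# uniform unit stack helper for metric tests
unitStack <- function(img, dy = 1, dz = 1, normalized = FALSE, prov = list())
    new("AcquiredStack", image = img, dy = dy, dz = dz,
        normalized = normalized, provenance = prov)
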