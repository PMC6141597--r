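# Image formation: PSF models, S = (I * F) (x) C, slit and widefield readout.

test_that("detection PSF kernels are normalized and symmetric", {
    g <- GridSpec(128, 128, 200, dx = 0.5)
    for (model in c("gaussian-approx", "scalar-defocus")) {
        det <- DetectionSpec(psfModel = model)
        k <- detectionPSF(det, g)
        expect_equal(sum(k), 1, tolerance = 1e-9)
        for (ax in 1:3) {
            flipped <- switch(ax,
                k[rev(seq_len(dim(k)[1])), , , drop = FALSE],
                k[, rev(seq_len(dim(k)[2])), , drop = FALSE],
                k[, , rev(seq_len(dim(k)[3])), drop = FALSE])
            expect_equal(as.vector(k), as.vector(flipped), tolerance = 1e-7)
        }
    }
    expect_error(detectionPSF(DetectionSpec(), GridSpec(4, 4, 4, dx = 0.5)),
                 "larger than grid")
})

test_that("gaussian-approx lateral width scales as 1/NA", {
    # anisotropic voxels: coarse along the (long) detection axis, fine
    # laterally so the second moment resolves the narrow kernel
    g <- GridSpec(256, 256, 64, dx = 1, dy = 0.1, dz = 0.5)
    sdOf <- function(na) {
        k <- detectionPSF(DetectionSpec(na = na), g)
        prof <- apply(k, 2, sum)
        y <- (seq_along(prof) - (length(prof) + 1) / 2) * g@dy
        sqrt(sum(prof * y^2) / sum(prof))
    }
    # closed form: sigma = 0.21 lambda / NA, so the ratio is exactly 0.5
    expect_equal(0.21 * 0.680 / 0.40, 0.5 * (0.21 * 0.680 / 0.20))
    expect_equal(sdOf(0.40) / sdOf(0.20), 0.5, tolerance = 1e-3)
})

test_that("fluorescence image formation is linear and respects F", {
    g <- GridSpec(40, 24, 30, dx = 1)
    ph <- buildPhantom(g)
    I <- array(stats::runif(40 * 24 * 30), c(40, 24, 30))
    # delta kernel: S = I exactly when F = 1
    expect_equal(fluorescenceImage(I, ph), I)
    # F = 0 everywhere -> S = 0
    dark <- buildPhantom(g, gelFluorescent = FALSE, fluorBackground = 0)
    expect_true(all(fluorescenceImage(I, dark) == 0))
    # linearity in I, with a real PSF
    det <- DetectionSpec(na = 0.4)
    S1 <- fluorescenceImage(I, ph, det)
    S2 <- fluorescenceImage(2 * I, ph, det)
    expect_equal(S2, 2 * S1, tolerance = 1e-12)
    # fluorophore voids (non-fluorescent spheres) remove signal
    phs <- buildPhantom(g, spheres = list(SphereSpec(c(0, 0, 15), 10)))
    expect_lt(sum(fluorescenceImage(I, phs)), sum(fluorescenceImage(I, ph)))
})

test_that("slit aperture reduces to widefield in its limits", {
    g <- tinyGrid(nz = 60)
    b <- BeamSpec(0.06, 0.06)
    det <- DetectionSpec(slitWidth = 20)
    src <- makeSourceField(b, 30, g)
    rec <- propagateBeam(src, buildPhantom(g),
                         PropagationConfig(b, 30, recordPlan = "camera",
                                           detection = det))
    wf <- widefieldImage(rec)
    # slit wider than the field: identical to widefield
    wide <- DetectionSpec(slitWidth = 1e4)
    expect_equal(applySlit(wf, 0, wide)@image, wf@image)
    # slit strictly off the beam: zero image wherever the beam had signal
    off <- applySlit(wf, 45, det)
    expect_true(all(off@image[abs(yCoords(g)) < 10, ] == 0))
    # confocal image never exceeds the widefield image
    sl <- applySlit(wf, 0, det)
    expect_true(all(sl@image <= wf@image + 1e-15))
    # widefield mode refuses the slit
    expect_error(applySlit(wf, 0, DetectionSpec(mode = "widefield")),
                 "widefieldImage")
})

test_that("beam translation translates the detected image (homogeneous gel)", {
    g <- tinyGrid(nz = 60)
    b <- BeamSpec(0.06, 0.06)
    det <- DetectionSpec()
    ph <- buildPhantom(g)
    cfg <- function(y) PropagationConfig(b, 30, recordPlan = "camera",
                                         detection = det, sourceY = y)
    img0 <- widefieldImage(propagateBeam(
        makeSourceField(b, 30, g), ph, cfg(0)))@image
    img5 <- widefieldImage(propagateBeam(
        makeSourceField(b, 30, g, sourceY = 5), ph, cfg(5)))@image
    shifted <- img0[c((nrow(img0) - 3):nrow(img0), 1:(nrow(img0) - 4)), ]
    expect_equal(img5, shifted, tolerance = 1e-9)
})

test_that("both PSF models agree on normalization identities and on the
           beam ordering of the occlusion metric", {
    # The two detection models differ structurally in their axial response
    # (optical sectioning vs laterally energy-conserving defocus), so the
    # absolute occlusion metric is model-dependent; what must hold for both
    # is the exact sphere-free normalization and the circular-vs-elliptical
    # ordering of the occluded focal signal.
    g <- GridSpec(120, 120, 370, dx = 1)
    ph <- occlusionPhantom(g)
    vals <- sapply(c("gaussian-approx", "scalar-defocus"), function(model) {
        det <- DetectionSpec(psfModel = model)
        empty <- runAcquisition(
            AcquisitionPlan("DSLM", beam = dslmBeam(), detection = det,
                            zFocus = 350, scanStep = 4,
                            scanRange = c(-8, 8)), emptyPhantom(ph))
        expect_lt(abs(focusRatio(empty, 350) - 1), 1e-6)
        vapply(list(dslmBeam(), mdslmBeam()), function(b) {
            plan <- AcquisitionPlan(if (naY(b) > naX(b)) "mDSLM" else "DSLM",
                                    beam = b, detection = det, zFocus = 350,
                                    scanStep = 4, scanRange = c(-8, 8))
            focusRatio(runAcquisition(plan, ph), 350)
        }, numeric(1))
    })
    expect_true(all(vals[2, ] > vals[1, ]))   # elliptical keeps more signal
})
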