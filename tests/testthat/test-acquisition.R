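# Acquisition orchestration: modes, scanning, tiling, sweeps.

test_that("scanned plans differ only in the beam; sheet plans only in the
           pivot set", {
    d <- AcquisitionPlan("DSLM")
    m <- AcquisitionPlan("mDSLM")
    for (s in c("detection", "zFocus", "scanStep", "scanRange", "scanWindow",
                "windowCenter", "normalize"))
        expect_equal(slot(d, s), slot(m, s))
    expect_equal(naX(d@beam), naX(m@beam))
    expect_gt(naY(m@beam), naY(d@beam))
    s1 <- AcquisitionPlan("SPIM")
    s2 <- AcquisitionPlan("mSPIM")
    expect_equal(s1@beam, s2@beam)
    expect_equal(s1@detection@mode, "widefield")
})

test_that("a single zero-angle pivot reproduces the static sheet exactly", {
    g <- tinyGrid(nz = 60)
    ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 3, 30), 12)))
    spim <- runAcquisition(AcquisitionPlan("SPIM", zFocus = 40), ph)
    mspim1 <- runAcquisition(AcquisitionPlan("mSPIM", zFocus = 40,
                                             pivotN = 1L), ph)
    expect_identical(stackImage(spim), stackImage(mspim1))
    # averaging genuinely distinct angles changes the image
    mspim <- runAcquisition(AcquisitionPlan("mSPIM", zFocus = 40,
                                            pivotHalfAngle = 4,
                                            pivotN = 3L), ph)
    expect_gt(max(abs(stackImage(mspim) - stackImage(spim))), 1e-4)
})

test_that("normalized empty-phantom acquisitions are unit images", {
    g <- tinyGrid(nz = 50)
    ph <- buildPhantom(g)
    scanned <- runAcquisition(
        AcquisitionPlan("DSLM", zFocus = 30, scanStep = 5,
                        scanRange = c(-10, 10)), ph)
    inside <- stackImage(scanned)[abs(yCoords(g)) < 8, ]
    expect_lt(max(abs(inside - 1)), 1e-6)
    sheet <- runAcquisition(AcquisitionPlan("SPIM", zFocus = 30), ph)
    expect_lt(max(abs(stackImage(sheet)[abs(yCoords(g)) < 40, ] - 1)), 1e-6)
})

test_that("the NA sweep is consistent with the plain scenario at the
           matching cell and records per-cell failures", {
    g <- GridSpec(96, 96, 200, dx = 1.25)
    ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 2, 60), 16)))
    direct <- singleBeamFocalRatio(BeamSpec(0.06, 0.06), ph, 170)
    sw <- runNASweep(0.06, c(0.06, 0.45), ph, 170,
                     metric = "focus_intensity")
    expect_equal(sw$value[1], direct, tolerance = 1e-12)
    expect_true(is.na(sw$value[2]))            # under-resolved at 1.25 um
    expect_match(sw$status[2], "under-resolved")
})

test_that("halving the scan step barely changes the scanned focal metric", {
    g <- GridSpec(120, 120, 370, dx = 1)
    ph <- occlusionPhantom(g)
    val <- function(step) {
        plan <- AcquisitionPlan("DSLM", beam = dslmBeam(), zFocus = 350,
                                scanStep = step, scanRange = c(-12, 12))
        focusRatio(runAcquisition(plan, ph), 350)
    }
    v2 <- val(2); v1 <- val(1)
    expect_lt(abs(v2 - v1) / v1, 0.02)
})

test_that("a single tile covering the whole depth equals the plain
           acquisition", {
    g <- tinyGrid(nz = 60)
    ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 2, 30), 10)))
    plan <- AcquisitionPlan("DSLM", zFocus = 37.5, scanStep = 5,
                            scanRange = c(-10, 10))
    whole <- runAcquisition(plan, ph)
    tiled <- runTiledZ(plan, ph, tileStep = 75, tileCenters = 37.5)
    expect_equal(stackImage(tiled), stackImage(whole), tolerance = 1e-12)
})

test_that("tile boundaries are seamless in a homogeneous phantom", {
    g <- tinyGrid(nz = 80)
    ph <- buildPhantom(g)
    plan <- AcquisitionPlan("DSLM", scanStep = 5, scanRange = c(-10, 10))
    tiled <- runTiledZ(plan, ph, tileStep = 50, tileCenters = c(25, 75))
    img <- stackImage(tiled)[abs(yCoords(g)) < 8, ]
    # normalized homogeneous acquisition: flat across every tile boundary
    jump <- abs(diff(t(img)))
    expect_lt(max(jump), 0.05)
})
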