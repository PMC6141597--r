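# Split-step propagation engine.

test_that("source field construction matches the waist definition", {
    g <- tinyGrid()
    # circular beam focused at the entry face: real, circularly symmetric
    b <- BeamSpec(0.08, 0.08)
    f <- makeSourceField(b, 0, g)
    u <- fieldMatrix(f)
    expect_lt(max(abs(Im(u))) / max(abs(Re(u))), 1e-9)
    expect_equal(Re(u), t(Re(u)), tolerance = 1e-12)
    expect_equal(fieldPower(f), 1, tolerance = 1e-12)
    # fitted 1/e^2 radius at the waist
    I <- Re(u)^2 + Im(u)^2
    xs <- xCoords(g)
    sig <- sqrt(sum(rowSums(I) * xs^2) / sum(I))
    expect_equal(2 * sig, beamWaist(0.08, 0.66), tolerance = 0.01)
    # elliptical beam at its waist is narrower along y than x
    fe <- makeSourceField(BeamSpec(0.06, 0.18), 0, g)
    Ie <- abs(fieldMatrix(fe))^2
    expect_lt(sum(colSums(Ie) * yCoords(g)^2) / sum(Ie),
              sum(rowSums(Ie) * xCoords(g)^2) / sum(Ie))
})

test_that("under-resolved beams and bad focus positions are rejected", {
    g <- tinyGrid()          # 1.25-um pitch
    expect_error(makeSourceField(BeamSpec(0.40, 0.40), 0, g),
                 "under-resolved")
    expect_error(makeSourceField(BeamSpec(0.06), 1e4, g), "outside the grid")
})

test_that("free-space propagation reproduces the analytic beam envelope", {
    # criterion-style check: fitted radii vs the hyperbolic profile with the
    # in-medium Rayleigh range implied by the carrier k = 2 pi n / lambda
    g <- GridSpec(128, 128, 360, dx = 1, dz = 1)
    b <- BeamSpec(0.06, 0.06)
    ph <- buildPhantom(g)
    zf <- 180
    src <- makeSourceField(b, zf, g)
    rec <- propagateBeam(src, ph,
                         PropagationConfig(b, zf, recordPlan = c("radii", "power")))
    zc <- zCoords(g)
    zRm <- b@mediumIndex * rayleighRange(b@naX, b@wavelength)
    depths <- zf + seq(-2, 2, length.out = 11) * zRm
    depths <- depths[depths > 2 & depths < max(zc)]
    expect_gte(length(depths), 11)
    for (d in depths) {
        iz <- which.min(abs(zc - d))
        wAna <- beamWaist(b@naX, b@wavelength) *
            sqrt(1 + ((zc[iz] - zf) / zRm)^2)
        expect_lt(abs(rec@radii[iz, 1] - wAna) / wAna, 0.02)
        expect_lt(abs(rec@radii[iz, 2] - wAna) / wAna, 0.02)
    }
    # minimum y-radius sits at the requested focus (within one step)
    expect_lt(abs(zc[which.min(rec@radii[, 2])] - zf), 1.5 * g@dz)
    # unitarity: per-slice power constant to much better than 0.5%
    expect_lt(max(abs(rec@power / rec@power[1] - 1)), 0.005)
})

test_that("normalization against a matching reference is exact", {
    g <- tinyGrid(nz = 80)
    b <- BeamSpec(0.06, 0.12)
    ph <- buildPhantom(g)
    src <- makeSourceField(b, 50, g)
    cfg <- PropagationConfig(b, 50, recordPlan = c("axial", "planeYZ"))
    rec <- propagateBeam(src, ph, cfg)
    ref <- unobstructedReference(src, ph, cfg)
    expect_lt(max(abs(normalizedMap(rec@axial, ref@axial) - 1)), 1e-9)
    expect_equal(focalIntensityRatio(rec, ref), 1, tolerance = 1e-9)
})

test_that("propagation is linear in source power", {
    g <- tinyGrid(nz = 60)
    b <- BeamSpec(0.06, 0.06)
    ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 0, 40), 12)))
    src <- makeSourceField(b, 50, g)
    src2 <- src
    src2@field <- src@field * 2
    cfg <- PropagationConfig(b, 50, recordPlan = c("axial", "camera"),
                             detection = DetectionSpec())
    r1 <- propagateBeam(src, ph, cfg)
    r2 <- propagateBeam(src2, ph, cfg)
    expect_equal(r2@axial, 4 * r1@axial, tolerance = 1e-12)
    expect_equal(r2@camera, 4 * r1@camera, tolerance = 1e-12)
})

test_that("an on-axis sphere preserves the y symmetry of the field", {
    g <- tinyGrid(nz = 100)
    b <- BeamSpec(0.06, 0.10)
    ph <- buildPhantom(g, spheres = list(SphereSpec(c(0, 0, 40), 14)))
    src <- makeSourceField(b, 80, g)
    rec <- propagateBeam(src, ph,
                         PropagationConfig(b, 80, recordPlan = "planeYZ"))
    img <- rec@planeYZ
    flipped <- img[rev(seq_len(nrow(img))), ]
    expect_lt(max(abs(img - flipped)) / max(img), 1e-9)
})

test_that("grid mismatches and step overrides are rejected", {
    g <- tinyGrid(nz = 40)
    b <- BeamSpec(0.06)
    src <- makeSourceField(b, 20, g)
    g2 <- GridSpec(64, 64, 40, dx = 1.25)
    expect_error(propagateBeam(src, buildPhantom(g2),
                               PropagationConfig(b, 20)),
                 "does not match")
    expect_error(propagateBeam(src, buildPhantom(g),
                               PropagationConfig(b, 20, dz = 0.4)),
                 "must equal the grid dz")
})

test_that("the elliptical beam keeps more focal intensity than the circular
           beam behind the occluding sphere", {
    expect_gt(coarseOcclusionRatio("mdslm"), coarseOcclusionRatio("dslm"))
})
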