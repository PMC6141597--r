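# Closed-form Gaussian-optics module.

test_that("waist and Rayleigh range reproduce hand-evaluated design values", {
    expect_equal(beamWaist(0.06, 0.660), 3.50141, tolerance = 1e-5)
    expect_equal(beamWaist(0.18, 0.660), 1.16714, tolerance = 1e-5)
    expect_equal(rayleighRange(0.06, 0.660), 58.356, tolerance = 1e-4)
    # confocal parameter 2 z_R for the standard sheet beam
    expect_equal(2 * rayleighRange(0.06, 0.660), 116.71, tolerance = 1e-4)
    # scaling laws are exact
    expect_equal(beamWaist(0.18, 0.660), beamWaist(0.06, 0.660) / 3)
    expect_equal(rayleighRange(0.12, 0.660), rayleighRange(0.06, 0.660) / 4)
})

test_that("beam radius follows the standard hyperbolic profile", {
    w0 <- beamWaist(0.06, 0.66)
    zR <- rayleighRange(0.06, 0.66)
    expect_equal(beamRadius(0, 0.06, 0.66), w0)
    expect_equal(beamRadius(zR, 0.06, 0.66), sqrt(2) * w0)
    expect_equal(beamRadius(-zR, 0.06, 0.66), sqrt(2) * w0)   # even in z
    # elliptical beam: y radius at the x Rayleigh range of an NA 0.06 beam
    wy <- beamRadius(rayleighRange(0.06, 0.66), 0.18, 0.66)
    expect_equal(wy, beamWaist(0.18, 0.66) * sqrt(1 + 81), tolerance = 1e-12)
    expect_equal(wy, 10.57, tolerance = 1e-3)
    # z_R ratio between axes is exactly (na_x/na_y)^2
    expect_equal(rayleighRange(0.18, 0.66) / rayleighRange(0.06, 0.66), 1 / 9)
})

test_that("transverse intensity is normalized and symmetric", {
    b <- BeamSpec(0.06, 0.18)
    w0x <- beamWaist(0.06, 0.66); w0y <- beamWaist(0.18, 0.66)
    expect_equal(beamIntensity(0, 0, 0, b), 2 / (pi * w0x * w0y))
    # 1/e^2 radius definition
    wx50 <- beamRadius(50, 0.06, 0.66)
    expect_equal(beamIntensity(wx50, 0, 50, b),
                 exp(-2) * beamIntensity(0, 0, 50, b))
    # numeric transverse integral equals 1 at the waist and at 2 z_R,x
    for (z in c(0, 2 * rayleighRange(0.06, 0.66))) {
        wx <- beamRadius(z, 0.06, 0.66); wy <- beamRadius(z, 0.18, 0.66)
        xs <- seq(-6 * wx, 6 * wx, length.out = 801)
        ys <- seq(-6 * wy, 6 * wy, length.out = 801)
        I <- outer(xs, ys, function(x, y) beamIntensity(x, y, z, b))
        integ <- sum(I) * diff(xs[1:2]) * diff(ys[1:2])
        expect_equal(integ, 1, tolerance = 1e-6)
    }
    # circular beam: swapping x and y leaves the intensity unchanged
    bc <- BeamSpec(0.1, 0.1)
    expect_equal(beamIntensity(1.3, -0.4, 25, bc),
                 beamIntensity(-0.4, 1.3, 25, bc))
})

test_that("pivot-angle equivalence and slit rule give the design numbers", {
    expect_equal(pivotHalfAngle(0.18), 10.37, tolerance = 1e-3)
    expect_equal(pivotHalfAngle(0), 0)
    expect_equal(pivotHalfAngle(0.20), 11.54, tolerance = 1e-3)
    expect_error(pivotHalfAngle(1), "\\[0, 1\\)")
    expect_equal(slitWidthRule(0.06, 0.660), 7.4276, tolerance = 1e-4)
    expect_equal(slitWidthRule(0.06, 0.660, factor = 0), 0)
})

test_that("domain errors are raised for invalid beam parameters", {
    expect_error(beamWaist(0, 0.66), "positive")
    expect_error(beamWaist(0.06, -1), "positive")
    expect_error(BeamSpec(0.5, 0.5, mediumIndex = 0.4), "mediumIndex")
    expect_error(beamIntensity(0, 0, 0, BeamSpec(0.06, 0)), "naY > 0")
})
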