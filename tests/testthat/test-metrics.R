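# Shadow, contrast and attenuation statistics.

test_that("focusRatio demands a normalized stack and reads the focal window", {
    img <- matrix(1, 40, 60)
    raw <- unitStack(img)
    expect_error(focusRatio(raw, 30), "normalized")
    norm <- unitStack(img, normalized = TRUE)
    expect_equal(focusRatio(norm, 30), 1)
    img2 <- img; img2[19:21, 29:31] <- 0.4
    expect_lt(focusRatio(unitStack(img2, normalized = TRUE), 29.5), 1)
})

test_that("sigma profile matches closed-form cases", {
    flat <- unitStack(matrix(1, 30, 20), prov = list(boundaryFraction = 0))
    expect_true(all(sigmaProfile(flat)$sigma == 0))
    alt <- unitStack(matrix(c(0.7, 1.3), 30, 20),
                     prov = list(boundaryFraction = 0))
    expect_equal(sigmaProfile(alt)$sigma, rep(0.3, 20), tolerance = 1e-12)
    expect_error(sigmaProfile(unitStack(matrix(1, 1, 20))), "single y row")
    # multiplicative rescaling of stack and reference cancels
    st <- matrix(stats::runif(600, 0.5, 1.5), 30, 20)
    rf <- matrix(stats::runif(600, 0.8, 1.2), 30, 20)
    s1 <- sigmaProfile(unitStack(st / rf, prov = list(boundaryFraction = 0)))
    s2 <- sigmaProfile(unitStack((3 * st) / (3 * rf),
                                 prov = list(boundaryFraction = 0)))
    expect_equal(s1$sigma, s2$sigma, tolerance = 1e-12)
})

test_that("contrast profile matches closed-form cases and stays in [0, 1]", {
    # peak 1.0 on pedestal 0.5 -> C = 1/3 with exact extrema
    img <- matrix(0.5, 20, 30); img[10, 5] <- 1
    st <- unitStack(img)
    cp <- contrastProfile(st, roiWidth = 10, exact = TRUE)
    expect_equal(cp$contrast[1], 1 / 3, tolerance = 1e-12)
    # a zero minimum gives C = 1; a constant ROI gives C = 0
    img2 <- matrix(1, 20, 30); img2[3, 2] <- 0
    expect_equal(contrastProfile(unitStack(img2), roiWidth = 10,
                                 exact = TRUE)$contrast[1], 1)
    expect_equal(contrastProfile(unitStack(matrix(2, 20, 30)),
                                 roiWidth = 10)$contrast, rep(0, 3))
    rnd <- unitStack(matrix(stats::runif(600), 20, 30))
    cc <- contrastProfile(rnd, roiWidth = 12)$contrast
    expect_true(all(cc >= 0 & cc <= 1))
    expect_error(contrastProfile(st, roiWidth = 2), "< 3 pixels")
})

test_that("attenuation correction recovers an imposed decay and is
           idempotent", {
    z <- (seq_len(200) - 0.5) * 2            # um, dz = 2
    decay <- exp(-10 * z / 1000)             # mu_s = 10 mm^-1
    img <- matrix(decay, 50, 200, byrow = TRUE)
    st <- unitStack(img, dz = 2)
    res <- attenuationCorrect(st)
    expect_equal(res$muS, 10, tolerance = 1e-6)
    # corrected stack is flat: re-fit gives mu_s ~ 0 (within 1e-3 mm^-1)
    refit <- attenuationCorrect(res$stack)
    expect_lt(abs(refit$muS), 1e-3)
    # scale invariance of the fitted coefficient
    res2 <- attenuationCorrect(unitStack(5 * img, dz = 2))
    expect_equal(res2$muS, res$muS, tolerance = 1e-9)
    # mu_s = 0 input returns unchanged
    flat <- unitStack(matrix(1, 50, 200), dz = 2)
    res0 <- attenuationCorrect(flat)
    expect_lt(abs(res0$muS), 1e-3)
    expect_equal(stackImage(res0$stack), stackImage(flat), tolerance = 1e-9)
    bad <- unitStack(matrix(c(rep(1, 100), rep(0, 100)), 2, 100,
                            byrow = TRUE) - 0.5)
    expect_error(attenuationCorrect(bad), "non-positive")
})

test_that("widening the slit towards widefield reduces the edge roll-off", {
    g <- GridSpec(120, 120, 450, dx = 1)
    ph <- buildPhantom(g)
    r20 <- scannedEdgeRolloff(mdslmBeam(), ph, 350,
                              detection = DetectionSpec(slitWidth = 20),
                              scanStep = 2)
    rInf <- scannedEdgeRolloff(mdslmBeam(), ph, 350,
                               detection = DetectionSpec(slitWidth = 1e4),
                               scanStep = 2)
    expect_lt(rInf, r20)
    # with no aperture loss only the detection defocus term remains
    expect_lt(rInf, 0.08)
    # edges outside the stack are rejected
    gShort <- GridSpec(120, 120, 360, dx = 1)
    stShort <- unitStack(matrix(1, 120, 360),
                         prov = list(boundaryFraction = 0.1))
    expect_error(edgeRolloff(stShort, mdslmBeam(), 350), "outside the stack")
})

test_that("metric tables round-trip through CSV with their metadata", {
    df <- data.frame(z = c(10, 20), sigma = c(0.1, 0.2))
    path <- tempfile(fileext = ".csv")
    writeMetricTable(df, path, meta = list(scenario = "demo", seed = 3))
    back <- readMetricTable(path)
    expect_equal(back$data, df)
    expect_equal(back$meta$scenario, "demo")
    expect_equal(back$meta$seed, "3")
})
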