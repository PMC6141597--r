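# Voxelized sphere-in-gel phantoms.

test_that("voxelized sphere volume converges to the analytic volume", {
    ana <- 4 / 3 * pi * 10^3
    # full-resolution voxelization (0.25-um pitch) of the 20-um sphere
    g25 <- GridSpec(96, 96, 96, dx = 0.25)
    ph <- buildPhantom(g25, spheres = list(SphereSpec(c(0, 0, 12), 20)))
    v25 <- voxelizedSphereVolume(ph)
    expect_lt(abs(v25 - ana) / ana, 0.02)
    # halving the pitch changes the voxelized volume by < 1%
    g50 <- GridSpec(48, 48, 48, dx = 0.5)
    v50 <- voxelizedSphereVolume(
        buildPhantom(g50, spheres = list(SphereSpec(c(0, 0, 12), 20))))
    expect_lt(abs(v25 - v50) / ana, 0.01)
})

test_that("empty phantoms are uniform and slices carry declared values only", {
    g <- GridSpec(24, 24, 30, dx = 1)
    ph <- buildPhantom(g, nBackground = 1.46)
    expect_null(refractiveSlice(ph, 7))
    expect_true(all(refractiveVolume(ph) == 1.46))
    expect_true(all(fluorVolume(ph) == 1))
    phs <- buildPhantom(g, spheres = list(SphereSpec(c(0, 2, 15), 10)))
    vals <- unique(as.vector(refractiveVolume(phs)))
    expect_setequal(vals, c(1.46, 1.59))
    f <- fluorVolume(phs)
    expect_setequal(unique(as.vector(f)), c(0, 1))
    # F = 0 exactly where n = 1.59
    expect_identical(f == 0, refractiveVolume(phs) == 1.59)
})

test_that("fluorescent-sphere phantoms invert the fluorophore map", {
    g <- GridSpec(24, 24, 30, dx = 1)
    ph <- buildPhantom(g, spheres = list(
        SphereSpec(c(0, 0, 15), 10, fluorescent = TRUE)),
        gelFluorescent = FALSE, fluorBackground = 0.1)
    f <- fluorVolume(ph)
    n <- refractiveVolume(ph)
    expect_true(all(f[n == 1.59] == 1))
    expect_true(all(f[n == 1.46] == 0.1))
})

test_that("phantom construction validates geometry", {
    g <- GridSpec(24, 24, 30, dx = 1)
    expect_error(buildPhantom(g, spheres = list(SphereSpec(c(0, 0, 2), 10))),
                 "bounds")
    expect_error(buildPhantom(g, spheres = list(
        SphereSpec(c(0, 0, 10), 8), SphereSpec(c(0, 2, 12), 8))),
        "overlap")
    # same geometry allowed when overlap is explicit
    expect_s4_class(buildPhantom(g, spheres = list(
        SphereSpec(c(0, 0, 10), 8), SphereSpec(c(0, 2, 12), 8)),
        allowOverlap = TRUE), "Phantom")
})

test_that("random sphere phantoms hit the requested fraction and are seeded", {
    g <- GridSpec(100, 100, 100, dx = 1)
    ph <- randomSpherePhantom(g, diameter = 6, volumeFraction = 0.001,
                              seed = 7)
    # expected count: round(0.001 * 1e6 / (4/3 pi 27)) = 9
    expect_length(phantomSpheres(ph), 9L)
    vol <- 100^3
    realized <- length(phantomSpheres(ph)) * 4 / 3 * pi * 27 / vol
    expect_lt(abs(realized - 0.001) / 0.001, 0.10)
    # determinism: identical seed gives voxel-identical phantoms
    ph2 <- randomSpherePhantom(g, diameter = 6, volumeFraction = 0.001,
                               seed = 7)
    expect_identical(
        lapply(phantomSpheres(ph), function(s) s@center),
        lapply(phantomSpheres(ph2), function(s) s@center))
    expect_identical(refractiveSlice(ph, 50), refractiveSlice(ph2, 50))
    ph3 <- randomSpherePhantom(g, diameter = 6, volumeFraction = 0.001,
                               seed = 8)
    expect_false(identical(
        lapply(phantomSpheres(ph), function(s) s@center),
        lapply(phantomSpheres(ph3), function(s) s@center)))
    # zero fraction gives the uniform phantom
    expect_length(phantomSpheres(
        randomSpherePhantom(g, volumeFraction = 0, seed = 1)), 0L)
    # generator leaves the caller's RNG stream untouched
    set.seed(123); before <- rnorm(1)
    set.seed(123); invisible(randomSpherePhantom(g, volumeFraction = 0.001,
                                                 seed = 5))
    expect_identical(rnorm(1), before)
})

test_that("infeasible packing fails with the achieved fraction reported", {
    g <- GridSpec(30, 30, 30, dx = 1)
    expect_error(randomSpherePhantom(g, diameter = 12,
                                     volumeFraction = 0.09, seed = 1,
                                     minGap = 6, maxAttempts = 50L),
                 "achieved fraction")
    expect_error(randomSpherePhantom(g, volumeFraction = 0.2, seed = 1),
                 "0.1")
})
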