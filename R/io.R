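## Configuration files, TIFF stack I/O, fixtures and run manifests.

#' Run configuration
#'
#' A validated, serializable description of one simulation run: scenario
#' name, preset, seed, grid, beam, detection, and (as plain validated lists,
#' materialized on demand) the phantom, acquisition plan and sweep sections.
#'
#' @slot scenario scenario name.
#' @slot preset "full", "scaled" or "coarse".
#' @slot seed integer seed.
#' @slot grid a [GridSpec-class].
#' @slot beam a [BeamSpec-class].
#' @slot detection a [DetectionSpec-class].
#' @slot phantom list phantom section (see [configPhantom()]), or empty.
#' @slot plan list acquisition section (see [configPlan()]), or empty.
#' @slot sweep list sweep section, or empty.
#' @slot outputDir output directory.
#' @export
setClass("RunConfig",
    representation(scenario = "character", preset = "character",
                   seed = "integer", grid = "GridSpec", beam = "BeamSpec",
                   detection = "DetectionSpec", phantom = "list",
                   plan = "list", sweep = "list", outputDir = "character"))

setMethod("show", "RunConfig", function(object) {
    cat(sprintf("RunConfig '%s' (preset %s, seed %d)\n", object@scenario,
                object@preset, object@seed))
    show(object@grid); show(object@beam); show(object@detection)
})

configSchema <- list(
    top = c("scenario", "preset", "seed", "grid", "beam", "detection",
            "phantom", "plan", "sweep", "output_dir"),
    grid = c("nx", "ny", "nz", "dx", "dy", "dz"),
    beam = c("na_x", "na_y", "wavelength", "medium_index"),
    detection = c("na", "lambda_em", "psf_model", "slit_width", "mode",
                  "pixel_pitch"),
    phantom = c("n_background", "gel_fluorescent", "fluor_background",
                "spheres", "random"),
    sphere = c("center", "diameter", "index", "fluorescent"),
    random = c("diameter", "volume_fraction", "seed", "min_gap",
               "edge_margin"),
    plan = c("mode", "z_focus", "scan_step", "scan_range", "scan_window",
             "window_center", "pivot_half_angle", "pivot_n", "normalize",
             "tile_step"),
    sweep = c("na_x_values", "na_y_values", "metric", "scan_step"))

checkKeys <- function(x, allowed, where, errs) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
        errs <- c(errs, sprintf("unknown key(s) in %s: %s", where,
                                paste(bad, collapse = ", ")))
    errs
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration (all lengths in um, NA dimensionless).
#' Unknown keys anywhere in the file are rejected, and every schema
#' violation is reported in one error.
#'
#' @param path path to a YAML configuration.
#' @return A [RunConfig-class].
#' @seealso [saveConfig()], [generateFixtures()]
#' @export
loadConfig <- function(path) {
    stopIfNot(file.exists(path), "config file not found: %s", path)
    raw <- yaml::read_yaml(path)
    errs <- character()
    errs <- checkKeys(raw, configSchema$top, "config", errs)
    for (sec in c("grid", "beam", "detection", "phantom", "plan", "sweep"))
        if (!is.null(raw[[sec]]))
            errs <- checkKeys(raw[[sec]], configSchema[[sec]], sec, errs)
    if (!is.null(raw$phantom$spheres))
        for (i in seq_along(raw$phantom$spheres))
            errs <- checkKeys(raw$phantom$spheres[[i]], configSchema$sphere,
                              sprintf("phantom$spheres[[%d]]", i), errs)
    if (!is.null(raw$phantom$random))
        errs <- checkKeys(raw$phantom$random, configSchema$random,
                          "phantom$random", errs)
    g <- raw$grid
    b <- raw$beam
    d <- raw$detection
    if (is.null(g)) errs <- c(errs, "missing required section: grid")
    if (is.null(b)) errs <- c(errs, "missing required section: beam")
    if (!is.null(b)) {
        if (is.null(b$na_x) || !is.numeric(b$na_x) || b$na_x <= 0)
            errs <- c(errs, "beam$na_x must be a positive number")
        if (!is.null(b$na_y) && (!is.numeric(b$na_y) || b$na_y < 0))
            errs <- c(errs, "beam$na_y must be a non-negative number")
    }
    if (length(errs))
        stop(paste(c("invalid configuration:", errs), collapse = "\n  "),
             call. = FALSE)
    grid <- GridSpec(g$nx, g$ny %||% g$nx, g$nz, g$dx, g$dy %||% g$dx,
                     g$dz %||% g$dx)
    beam <- BeamSpec(b$na_x, b$na_y %||% b$na_x, b$wavelength %||% 0.660,
                     b$medium_index %||% 1.46)
    det <- if (is.null(d)) DetectionSpec() else
        DetectionSpec(na = d$na %||% 0.40, lambdaEm = d$lambda_em %||% 0.680,
                      psfModel = d$psf_model %||% "gaussian-approx",
                      slitWidth = d$slit_width %||% 20,
                      mode = d$mode %||% "confocal-line",
                      pixelPitch = d$pixel_pitch %||% 0.77)
    new("RunConfig", scenario = raw$scenario %||% "unnamed",
        preset = raw$preset %||% "scaled",
        seed = as.integer(raw$seed %||% 1L), grid = grid, beam = beam,
        detection = det, phantom = raw$phantom %||% list(),
        plan = raw$plan %||% list(), sweep = raw$sweep %||% list(),
        outputDir = raw$output_dir %||% ".")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a run configuration to YAML
#'
#' Writes a [RunConfig-class] so that [loadConfig()] reproduces an identical
#' object (lossless round trip).
#'
#' @param config a [RunConfig-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
saveConfig <- function(config, path) {
    g <- config@grid; b <- config@beam; d <- config@detection
    out <- list(
        scenario = config@scenario, preset = config@preset,
        seed = config@seed,
        grid = list(nx = g@nx, ny = g@ny, nz = g@nz, dx = g@dx, dy = g@dy,
                    dz = g@dz),
        beam = list(na_x = b@naX, na_y = b@naY, wavelength = b@wavelength,
                    medium_index = b@mediumIndex),
        detection = list(na = d@na, lambda_em = d@lambdaEm,
                         psf_model = d@psfModel, slit_width = d@slitWidth,
                         mode = d@mode, pixel_pitch = d@pixelPitch))
    if (length(config@phantom)) out$phantom <- config@phantom
    if (length(config@plan)) out$plan <- config@plan
    if (length(config@sweep)) out$sweep <- config@sweep
    out$output_dir <- config@outputDir
    writeLines(yaml::as.yaml(out, precision = 15), path)
    invisible(path)
}

#' Materialize the phantom of a configuration
#'
#' Builds the [Phantom-class] described by a config's phantom section:
#' either an explicit sphere list or a seeded random small-sphere field.
#'
#' @param config a [RunConfig-class].
#' @return A [Phantom-class].
#' @export
configPhantom <- function(config) {
    p <- config@phantom
    nBg <- p$n_background %||% 1.46
    if (!is.null(p$random)) {
        r <- p$random
        return(randomSpherePhantom(config@grid,
                                   diameter = r$diameter %||% 6,
                                   volumeFraction = r$volume_fraction %||% 0.001,
                                   seed = r$seed %||% config@seed,
                                   minGap = r$min_gap %||% 0,
                                   nBackground = nBg,
                                   edgeMargin = r$edge_margin %||% 0))
    }
    spheres <- lapply(p$spheres %||% list(), function(s)
        SphereSpec(unlist(s$center), s$diameter, s$index %||% 1.59,
                   s$fluorescent %||% FALSE))
    buildPhantom(config@grid, nBg, spheres,
                 gelFluorescent = p$gel_fluorescent %||% TRUE,
                 fluorBackground = p$fluor_background %||% 0)
}

#' Materialize the acquisition plan of a configuration
#'
#' @param config a [RunConfig-class].
#' @return An [AcquisitionPlan-class].
#' @export
configPlan <- function(config) {
    pl <- config@plan
    stopIfNot(length(pl) > 0 && !is.null(pl$mode),
              "config '%s' has no plan section", config@scenario)
    AcquisitionPlan(pl$mode, beam = config@beam,
                    detection = config@detection,
                    zFocus = pl$z_focus %||% 350,
                    scanStep = pl$scan_step %||% 0.25,
                    scanRange = unlist(pl$scan_range %||%
                                       c(NA_real_, NA_real_)),
                    scanWindow = pl$scan_window %||% NA_real_,
                    windowCenter = pl$window_center %||% 0,
                    pivotHalfAngle = pl$pivot_half_angle %||% 10,
                    pivotN = pl$pivot_n %||% 21L,
                    normalize = pl$normalize %||% TRUE)
}

## ---------------------------------------------------------------------------
## TIFF stacks
## ---------------------------------------------------------------------------

#' Write an image stack as 32-bit TIFF with a metadata sidecar
#'
#' Writes an [AcquiredStack-class] (one page), a matrix (one page) or a 3D
#' array (one page per z) as 32-bit TIFF. Values are stored scaled into
#' [0, 1]; the scale factor, pitches, axis convention and normalization
#' state go to a YAML sidecar (\code{<path>.yaml}) so [readStack()]
#' restores physical values.
#'
#' @param stack an [AcquiredStack-class], matrix or 3D array.
#' @param path output TIFF path.
#' @param meta extra metadata to record in the sidecar.
#' @return The path, invisibly.
#' @export
writeStack <- function(stack, path, meta = list()) {
    if (is(stack, "AcquiredStack")) {
        data <- stack@image
        meta <- c(meta, list(dy = stack@dy, dz = stack@dz,
                             normalized = stack@normalized,
                             mode = stack@provenance$mode %||% "unknown"))
        pages <- list(data)
    } else if (is.matrix(stack)) {
        data <- stack
        pages <- list(data)
    } else if (is.array(stack) && length(dim(stack)) == 3) {
        data <- stack
        pages <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
    } else stop("writeStack: unsupported input", call. = FALSE)
    scale <- max(abs(unlist(lapply(pages, max))), 1e-300)
    tiff::writeTIFF(lapply(pages, function(p) pmax(p, 0) / scale), path,
                    bits.per.sample = 32L)
    side <- c(list(axes = "rows=y(scan), cols=z(propagation), pages=z or planes",
                   scale = scale, pages = length(pages)), meta)
    writeLines(yaml::as.yaml(side, precision = 15),
               paste0(path, ".yaml"))
    invisible(path)
}

#' Read a stack written by [writeStack()]
#'
#' @param path TIFF path.
#' @return A list with \code{data} (matrix or 3D array, physical values) and
#'   \code{meta} (the sidecar list).
#' @export
readStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- yaml::read_yaml(paste0(path, ".yaml"))
    scale <- meta$scale %||% 1
    pages <- lapply(pages, function(p) p * scale)
    data <- if (length(pages) == 1) pages[[1]] else
        array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    list(data = data, meta = meta)
}

## ---------------------------------------------------------------------------
## Fixtures and manifests
## ---------------------------------------------------------------------------

#' Write a reproducibility manifest
#'
#' Records the config hash (MD5 of its YAML serialization), package version,
#' preset, seed and produced files as JSON, written exactly once per run.
#'
#' @param path manifest path (.json).
#' @param config a [RunConfig-class] or NULL.
#' @param seed integer seed of the run.
#' @param preset preset name.
#' @param files character vector of produced files.
#' @param extra named list of additional entries.
#' @return The manifest list, invisibly.
#' @export
writeRunManifest <- function(path, config = NULL, seed = NA_integer_,
                             preset = NA_character_, files = character(),
                             extra = list()) {
    stopIfNot(!file.exists(path),
              "manifest already exists (written exactly once per run): %s",
              path)
    hash <- NA_character_
    if (!is.null(config)) {
        tmp <- tempfile(fileext = ".yaml")
        saveConfig(config, tmp)
        hash <- unname(tools::md5sum(tmp))
        unlink(tmp)
    }
    man <- c(list(config_hash = hash,
                  package = "lightSheetSim",
                  version = as.character(utils::packageVersion("lightSheetSim")),
                  preset = preset, seed = seed, files = files), extra)
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(man)
}

fixtureConfig <- function(scenario, preset, seed, beam, plan = list(),
                          sweep = list(), phantom = "sphere",
                          zExtent = 370) {
    grid <- presetGrid(preset, zExtent = zExtent)
    ph <- switch(phantom,
        sphere = list(n_background = 1.46, gel_fluorescent = TRUE,
                      spheres = list(list(center = c(0, 2, 125),
                                          diameter = 20, index = 1.59,
                                          fluorescent = FALSE))),
        random = list(n_background = 1.46, gel_fluorescent = TRUE,
                      random = list(diameter = 6, volume_fraction = 0.002,
                                    seed = seed, min_gap = 1)),
        none = list(n_background = 1.46, gel_fluorescent = TRUE))
    new("RunConfig", scenario = scenario, preset = preset,
        seed = as.integer(seed), grid = grid, beam = beam,
        detection = DetectionSpec(), phantom = ph, plan = plan,
        sweep = sweep, outputDir = ".")
}

#' Generate the shipped scenario fixtures
#'
#' Writes the runnable scenario configurations — single-beam occlusion
#' (circular and elliptical), scanned occlusion, the NA sweep pair, the
#' seeded small-sphere field, and a synthetic attenuation-recovery stack
#' with a known scattering coefficient — plus a manifest. Deterministic for
#' a given seed.
#'
#' @param seed integer seed.
#' @param outDir output directory (created if needed).
#' @param preset grid preset for the configs.
#' @return Character vector of written files, invisibly.
#' @export
generateFixtures <- function(seed = 1L, outDir = ".", preset = "scaled") {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    put <- function(cfg, name) {
        p <- file.path(outDir, paste0(name, ".yaml"))
        saveConfig(cfg, p)
        files <<- c(files, p)
    }
    put(fixtureConfig("occlusion_beam_dslm", preset, seed, dslmBeam()), "occlusion_beam_dslm")
    put(fixtureConfig("occlusion_beam_mdslm", preset, seed, mdslmBeam()), "occlusion_beam_mdslm")
    scanPlan <- list(mode = "DSLM", z_focus = 350, scan_step = 2,
                     scan_window = 30, window_center = 0, normalize = TRUE)
    put(fixtureConfig("occlusion_scan_dslm", preset, seed, dslmBeam(),
                      plan = scanPlan), "occlusion_scan_dslm")
    scanPlan$mode <- "mDSLM"
    put(fixtureConfig("occlusion_scan_mdslm", preset, seed, mdslmBeam(),
                      plan = scanPlan), "occlusion_scan_mdslm")
    put(fixtureConfig("na_sweep_focus", preset, seed, dslmBeam(),
                      sweep = list(na_x_values = seq(0.03, 0.24, by = 0.03),
                                   na_y_values = seq(0, 0.24, by = 0.03),
                                   metric = "focus_intensity")),
        "na_sweep_focus")
    put(fixtureConfig("na_sweep_edge", preset, seed, dslmBeam(),
                      sweep = list(na_x_values = seq(0.03, 0.24, by = 0.03),
                                   na_y_values = seq(0, 0.24, by = 0.03),
                                   metric = "edge_signal"),
                      phantom = "none", zExtent = 450), "na_sweep_edge")
    put(fixtureConfig("bead_field_tiled", preset, seed, dslmBeam(),
                      plan = list(mode = "DSLM", scan_step = 2,
                                  tile_step = 50, normalize = TRUE),
                      phantom = "random"), "bead_field_tiled")

    ## synthetic attenuation stack: imposed mu_s = 10 mm^-1, 1% noise
    muS <- 10
    nyS <- 64L; nzS <- 200L; dzS <- 2
    z <- (seq_len(nzS) - 0.5) * dzS
    stackPath <- file.path(outDir, "attenuation_synthetic.tif")
    img <- withSeed(seed, {
        noise <- matrix(stats::rnorm(nyS * nzS, 0, 0.01), nyS, nzS)
        sweep(matrix(1, nyS, nzS), 2, exp(-muS * z / 1000), "*") * (1 + noise)
    })
    writeStack(img, stackPath,
               meta = list(synthetic = TRUE, imposed_mu_s = muS,
                           dy = 1, dz = dzS, noise_sd = 0.01, seed = seed))
    files <- c(files, stackPath)
    manPath <- file.path(outDir, "fixtures_manifest.json")
    if (file.exists(manPath)) unlink(manPath)
    writeRunManifest(manPath, seed = seed, preset = preset,
                     files = basename(files),
                     extra = list(imposed_mu_s = muS))
    invisible(c(files, manPath))
}
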