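## The quantitative shadowing / contrast / attenuation statistics.

stackZ <- function(stack) {
    if (!is.null(stack@provenance$zKept)) stack@provenance$zKept
    else (seq_len(ncol(stack@image)) - 0.5) * stack@dz
}

stackY <- function(stack) {
    (seq_len(nrow(stack@image)) - (nrow(stack@image) + 1) / 2) * stack@dy
}

#' Focal intensity ratio of a normalized stack
#'
#' The normalized value at the on-axis focal position: the mean over a small
#' window (default 3 x 3 pixels) centred at (y = 0, z = zFocus) of a stack
#' normalized against its sphere-free reference. 1 means unobstructed.
#'
#' @param stack a normalized [AcquiredStack-class].
#' @param zFocus focus depth, um.
#' @param window window size in pixels per axis.
#' @return Numeric scalar.
#' @export
focusRatio <- function(stack, zFocus, window = 3) {
    stopIfNot(stack@normalized,
              "focusRatio: stack must be normalized against its sphere-free reference")
    zc <- stackZ(stack)
    stopIfNot(zFocus >= min(zc) && zFocus <= max(zc),
              "focusRatio: zFocus = %g um outside the stack depth", zFocus)
    iy <- nearestIndices(stackY(stack), 0, window)
    iz <- nearestIndices(zc, zFocus, window)
    mean(stack@image[iy, iz])
}

#' Normalized focal intensity from a static-beam record pair
#'
#' The mean over the on-axis focal window of the element-wise ratio of an
#' obstructed run's axial intensity patch to its sphere-free reference.
#'
#' @param rec,ref [IntensityRecord-class] pair recorded with the "axial"
#'   plan (obstructed run and its reference).
#' @param window window size in pixels per axis (x, y and z).
#' @return Numeric scalar (1 = unobstructed).
#' @export
focalIntensityRatio <- function(rec, ref, window = 3) {
    stopIfNot(length(rec@axial) > 0 && length(ref@axial) > 0,
              "records need the \"axial\" record plan")
    norm <- normalizedMap(rec@axial, ref@axial)
    d <- dim(norm)
    izF <- max(1L, min(d[3], round(rec@meta$zFocus / rec@meta$dz + 0.5)))
    iz <- intersect(izF + seq(-(window %/% 2), window %/% 2), seq_len(d[3]))
    i1 <- seq_len(min(window, d[1]))
    i2 <- seq_len(min(window, d[2]))
    mean(norm[i1, i2, iz])
}

#' Shadowing severity profile sigma_I,y(z)
#'
#' Per depth z, the population standard deviation of the normalized intensity
#' across the scan axis y, within an analysis band that excludes the
#' absorbing-boundary margin. The statistic summarizing streak/shadow
#' severity: 0 for a perfectly uniform illumination.
#'
#' @param stack a normalized [AcquiredStack-class].
#' @param marginFraction fraction of the y extent excluded at each edge
#'   (defaults to the run's absorbing-boundary fraction, or 0.1).
#' @return A data.frame with columns z (um) and sigma.
#' @export
sigmaProfile <- function(stack, marginFraction = NULL) {
    img <- stack@image
    stopIfNot(nrow(img) > 1, "sigmaProfile: stack has a single y row")
    if (is.null(marginFraction))
        marginFraction <- if (!is.null(stack@provenance$boundaryFraction))
            stack@provenance$boundaryFraction else 0.1
    ny <- nrow(img)
    keep <- seq_len(ny)
    if (marginFraction > 0) {
        m <- floor(ny * marginFraction)
        if (ny - 2 * m < 2) stop("sigmaProfile: margin leaves < 2 rows",
                                 call. = FALSE)
        keep <- (m + 1):(ny - m)
    }
    sub <- img[keep, , drop = FALSE]
    mu <- colMeans(sub)
    sig <- sqrt(colMeans(sub^2) - mu^2)
    data.frame(z = stackZ(stack), sigma = pmax(sig, 0))
}

#' Contrast profile C(z)
#'
#' Michelson contrast \eqn{C = (I_{max} - I_{min}) / (I_{max} + I_{min})}
#' per axial region of interest of width \code{roiWidth}. By default the
#' extrema are the 1st/99th percentiles of the ROI (robust to isolated hot
#' pixels); set \code{exact = TRUE} for true extrema.
#'
#' @param stack an [AcquiredStack-class].
#' @param roiWidth ROI width along z, um (must span >= 3 pixels).
#' @param exact use exact extrema instead of percentiles.
#' @param probs the robust percentile pair.
#' @return A data.frame with columns z (ROI centre, um) and contrast.
#' @export
contrastProfile <- function(stack, roiWidth = 20, exact = FALSE,
                            probs = c(0.01, 0.99)) {
    zc <- stackZ(stack)
    nPix <- floor(roiWidth / stack@dz)
    stopIfNot(nPix >= 3, "contrastProfile: roiWidth spans %d < 3 pixels", nPix)
    starts <- seq(1, length(zc) - nPix + 1, by = nPix)
    out <- data.frame(z = numeric(length(starts)),
                      contrast = numeric(length(starts)))
    for (i in seq_along(starts)) {
        cols <- starts[i]:(starts[i] + nPix - 1)
        roi <- stack@image[, cols]
        ext <- if (exact) range(roi) else
            stats::quantile(roi, probs, names = FALSE, type = 7)
        lo <- ext[1]; hi <- ext[2]
        out$z[i] <- mean(zc[cols])
        out$contrast[i] <- if (hi + lo <= 0) 0 else (hi - lo) / (hi + lo)
    }
    out
}

#' Field-edge signal roll-off
#'
#' \code{1 - mean(signal at z_focus +/- z_edge) / signal(z_focus)} read on a
#' scanned, slit-apertured sphere-free stack at y = 0, where the field edge
#' \code{z_edge} is the in-medium Rayleigh range of the sheet-forming axis
#' (\code{mediumIndex * pi w0x^2 / lambda} — the depth where the propagating
#' sheet has expanded by sqrt(2)).
#'
#' @param stack an [AcquiredStack-class] from a sphere-free scanned run.
#' @param beam the [BeamSpec-class] of the run.
#' @param zFocus focus depth, um.
#' @param window readout window, pixels.
#' @return Roll-off fraction (0 = flat field).
#' @export
edgeRolloff <- function(stack, beam, zFocus, window = 3) {
    zR <- beam@mediumIndex * rayleighRange(beam@naX, beam@wavelength)
    zc <- stackZ(stack)
    edges <- zFocus + c(-zR, zR)
    stopIfNot(all(edges >= min(zc) & edges <= max(zc)),
              "edgeRolloff: field edges (z = %g, %g um) outside the stack",
              edges[1], edges[2])
    iy <- nearestIndices(stackY(stack), 0, window)
    val <- function(z) mean(stack@image[iy, nearestIndices(zc, z, window)])
    1 - mean(c(val(edges[1]), val(edges[2]))) / val(zFocus)
}

#' Exponential attenuation correction
#'
#' Estimates the scattering attenuation of illumination with depth and
#' flattens it: the median intensity per z is smoothed with a moving-average
#' window, fitted in log space to \eqn{I = e^{-\mu_s z}} by ordinary least
#' squares, and the stack is multiplied by \eqn{e^{+\mu_s z}}.
#'
#' @param stack an [AcquiredStack-class] with strictly positive per-depth
#'   medians.
#' @param smoothWindow moving-average window, pixels.
#' @return A list with elements \code{stack} (corrected) and \code{muS}
#'   (fitted attenuation coefficient, mm^-1).
#' @examples
#' img <- matrix(exp(-10 * (1:100) / 1000), 40, 100, byrow = TRUE)
#' st  <- new("AcquiredStack", image = img, dy = 1, dz = 1,
#'            normalized = FALSE, provenance = list())
#' attenuationCorrect(st)$muS   # ~10 mm^-1
#' @export
attenuationCorrect <- function(stack, smoothWindow = 10) {
    med <- apply(stack@image, 2, stats::median)
    stopIfNot(all(med > 0),
              "attenuationCorrect: non-positive median at %d depth(s)",
              sum(med <= 0))
    sm <- movingAverage(med, smoothWindow)
    zmm <- stackZ(stack) / 1000            # um -> mm
    fit <- stats::lm.fit(cbind(1, zmm), log(sm))
    stopIfNot(all(is.finite(fit$coefficients)),
              "attenuationCorrect: exponential fit failed")
    muS <- -fit$coefficients[2]
    corr <- sweep(stack@image, 2, exp(muS * zmm), "*")
    out <- stack
    out@image <- corr
    out@provenance$attenuationCorrected <- TRUE
    out@provenance$muS <- unname(muS)
    list(stack = out, muS = unname(muS))
}

#' Write / read a metric table as CSV with a metadata header
#'
#' The header block is written as commented \code{# key: value} lines before
#' the CSV body, recording provenance (scenario, preset, config hash, seed).
#'
#' @param df a data.frame of metrics.
#' @param path output path.
#' @param meta named list of scalar metadata.
#' @return \code{writeMetricTable}: the path, invisibly.
#'   \code{readMetricTable}: a list with \code{data} and \code{meta}.
#' @export
writeMetricTable <- function(df, path, meta = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
        writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
    utils::write.csv(df, con, row.names = FALSE)
    invisible(path)
}

#' @rdname writeMetricTable
#' @export
readMetricTable <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta <- list()
    for (h in hdr) {
        kv <- sub("^#\\s*", "", lines[h])
        key <- sub(":.*$", "", kv)
        meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
    }
    body <- if (length(hdr)) lines[-hdr] else lines
    data <- utils::read.csv(text = paste(body, collapse = "\n"))
    list(data = data, meta = meta)
}
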