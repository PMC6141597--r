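## Image formation: S = (I * F) (x) C with widefield or confocal-slit readout.
##
## The collection objective looks along x; the camera records the yz plane.
## The detected image is the PSF-convolved emitted signal evaluated on the
## camera focal plane x = 0 (the beam-axis plane). Because every scenario
## metric is normalized against a matching sphere-free reference run, the
## absolute focal-plane choice cancels out of all reported quantities.

psfSigmas <- function(det) {
    list(lat = det@latC * det@lambdaEm / det@na,
         ax = det@axC * det@mediumIndex * det@lambdaEm / det@na^2)
}

#' Collection-objective 3D PSF kernel
#'
#' Returns a normalized (sums to 1) 3D intensity PSF with its optical axis
#' along x. The \code{gaussian-approx} model is a separable Gaussian with
#' lateral sigma \code{latC * lambda_em / NA} and axial sigma
#' \code{axC * n * lambda_em / NA^2}. The \code{scalar-defocus} model builds
#' each x slice from defocused-pupil scalar diffraction (each slice carries
#' equal energy, the laterally energy-conserving widefield behaviour).
#'
#' @param det a [DetectionSpec-class].
#' @param grid a [GridSpec-class] supplying the voxel pitches (the kernel
#'   must fit inside the grid).
#' @return A numeric 3D array (x, y, z), summing to 1.
#' @examples
#' g <- GridSpec(128, 128, 200, dx = 0.5)
#' psf <- detectionPSF(DetectionSpec(), g)
#' sum(psf)
#' @export
detectionPSF <- function(det, grid) {
    validObject(det); validObject(grid)
    sg <- psfSigmas(det)
    if (det@psfModel == "gaussian-approx") {
        kx <- gaussianKernel1D(sg$ax, grid@dx)
        ky <- gaussianKernel1D(sg$lat, grid@dy)
        kz <- gaussianKernel1D(sg$lat, grid@dz)
        kern <- outer(outer(kx, ky), kz)
    } else {
        xMax <- 4 * det@mediumIndex * det@lambdaEm / det@na^2
        nxk <- 2L * floor(xMax / grid@dx) + 1L
        defoc <- (seq_len(nxk) - (nxk + 1) / 2) * grid@dx
        slices <- lapply(abs(defoc), defocusKernel, det = det,
                         dy = grid@dy, dz = grid@dz)
        nyk <- max(vapply(slices, nrow, 1L))
        nzk <- max(vapply(slices, ncol, 1L))
        kern <- array(0, c(nxk, nyk, nzk))
        for (i in seq_len(nxk)) {
            s <- slices[[i]]
            oy <- (nyk - nrow(s)) %/% 2
            oz <- (nzk - ncol(s)) %/% 2
            kern[i, oy + seq_len(nrow(s)), oz + seq_len(ncol(s))] <-
                s / (nxk * sum(s))
        }
    }
    d <- dim(kern)
    stopIfNot(d[1] <= grid@nx && d[2] <= grid@ny && d[3] <= grid@nz,
              "detectionPSF: kernel (%d x %d x %d) larger than grid",
              d[1], d[2], d[3])
    kern / sum(kern)
}

## scalar diffraction kernel of a circular pupil at one defocus distance,
## sampled at (dy, dz); normalized to sum 1
defocusKernel <- function(defocus, det, dy, dz) {
    kMed <- 2 * pi * det@mediumIndex / det@lambdaEm
    kCut <- 2 * pi * det@na / det@lambdaEm
    blur <- defocus * tan(asin(det@na / det@mediumIndex))
    half <- max(3 * blur, 3 * det@lambdaEm / det@na, 4 * max(dy, dz))
    n1 <- 2L * ceiling(half / dy) + 1L
    n2 <- 2L * ceiling(half / dz) + 1L
    n1 <- max(n1, 16L); n2 <- max(n2, 16L)
    ky <- 2 * pi * fftFreq(n1, dy)
    kz <- 2 * pi * fftFreq(n2, dz)
    kr2 <- outer(ky^2, kz^2, "+")
    pupil <- kr2 <= kCut^2
    kax <- sqrt(pmax(kMed^2 - kr2, 0))
    h <- stats::fft(pupil * exp(1i * kax * defocus), inverse = TRUE)
    psf <- Re(h)^2 + Im(h)^2
    ## centre the kernel (fft origin is at [1, 1])
    psf <- rollRows(psf, floor(n1 / 2))
    psf <- t(rollRows(t(psf), floor(n2 / 2)))
    psf / sum(psf)
}

#' Emitted-signal volume S = (I * F) (x) C
#'
#' Multiplies an illumination intensity volume by the phantom's fluorophore
#' map and convolves with the collection PSF ("same" extent, zero padding).
#' Intended for small volumes (tests, inspection); full-scale runs stream the
#' detection weights through [propagateBeam()] instead.
#'
#' @param intensity numeric 3D array I(x, y, z) on the phantom grid.
#' @param phantom a [Phantom-class].
#' @param det a [DetectionSpec-class], or NULL for an identity (delta) kernel.
#' @return Numeric 3D array S of the same shape.
#' @export
fluorescenceImage <- function(intensity, phantom, det = NULL) {
    grid <- phantom@grid
    stopIfNot(identical(dim(intensity), c(grid@nx, grid@ny, grid@nz)),
              "fluorescenceImage: intensity dims do not match the phantom grid")
    S <- intensity * fluorVolume(phantom)
    if (is.null(det)) return(S)
    kern <- detectionPSF(det, grid)
    convolve3Same(S, kern)
}

## 3D linear ("same") convolution via zero-padded FFT
convolve3Same <- function(vol, kern) {
    dv <- dim(vol); dk <- dim(kern)
    dp <- dv + dk - 1L
    pv <- array(0, dp); pv[seq_len(dv[1]), seq_len(dv[2]), seq_len(dv[3])] <- vol
    pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- kern
    full <- Re(stats::fft(stats::fft(pv) * stats::fft(pk), inverse = TRUE)) /
        prod(dp)
    off <- (dk - 1L) %/% 2L
    full[off[1] + seq_len(dv[1]), off[2] + seq_len(dv[2]),
         off[3] + seq_len(dv[3])]
}

#' Widefield camera image
#'
#' The camera-plane yz image with no slit masking: the emitted-signal volume
#' evaluated at the detection focal plane x = 0 (for a 3D signal volume), or
#' the lateral-PSF-blurred camera accumulator of an [IntensityRecord-class].
#'
#' @param signal a 3D emitted-signal array (x, y, z) or an
#'   [IntensityRecord-class] recorded with the "camera" plan.
#' @param det the [DetectionSpec-class] used (needed for the record path).
#' @param grid the [GridSpec-class] (array path; pitches for the image).
#' @return A [CameraImage-class].
#' @export
widefieldImage <- function(signal, det = NULL, grid = NULL) {
    if (is(signal, "IntensityRecord")) {
        det <- if (is.null(det)) signal@meta$detection else det
        img <- blurCameraAccumulator(signal, det)
        return(new("CameraImage", image = img, dy = signal@grid@dy,
                   dz = signal@grid@dz,
                   provenance = list(mode = "widefield",
                                     sourceY = signal@meta$sourceY)))
    }
    stopIfNot(is.array(signal) && length(dim(signal)) == 3,
              "widefieldImage: expected a 3D signal array or IntensityRecord")
    stopIfNot(!is.null(grid), "widefieldImage: 'grid' needed for array input")
    ix <- nearestIndices(xCoords(grid), 0, 2)
    img <- apply(signal[ix, , , drop = FALSE], c(2, 3), mean)
    new("CameraImage", image = img, dy = grid@dy, dz = grid@dz,
        provenance = list(mode = "widefield"))
}

## lateral blur of the streamed camera accumulator
blurCameraAccumulator <- function(rec, det) {
    stopIfNot(length(rec@camera) > 0,
              "record has no 'camera' track; add \"camera\" to the record plan")
    grid <- rec@grid
    if (det@psfModel == "scalar-defocus" && !is.null(rec@meta$cameraBins)) {
        img <- matrix(0, grid@ny, grid@nz)
        for (b in seq_along(rec@meta$cameraBins)) {
            kb <- defocusKernel(abs(rec@meta$binCenters[b]), det,
                                grid@dy, grid@dz)
            img <- img + conv2Same(rec@meta$cameraBins[[b]], kb)
        }
        img
    } else {
        sg <- psfSigmas(det)
        blurSeparable(rec@camera,
                      gaussianKernel1D(sg$lat, grid@dy),
                      gaussianKernel1D(sg$lat, grid@dz))
    }
}

## 2D linear ("same") convolution via zero-padded FFT
conv2Same <- function(m, kern) {
    dm <- dim(m); dk <- dim(kern)
    dp <- dm + dk - 1L
    pm <- matrix(0, dp[1], dp[2]); pm[seq_len(dm[1]), seq_len(dm[2])] <- m
    pk <- matrix(0, dp[1], dp[2]); pk[seq_len(dk[1]), seq_len(dk[2])] <- kern
    full <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) /
        prod(dp)
    off <- (dk - 1L) %/% 2L
    full[off[1] + seq_len(dm[1]), off[2] + seq_len(dm[2])]
}

#' Confocal-slit aperture
#'
#' Masks a camera-plane image to the hard rectangular slit
#' \code{|y - beamY| <= slitWidth / 2} (pixel centres inside the slit are
#' kept, all others zeroed), modelling the rolling-shutter line detector
#' synchronized to the scanned beam.
#'
#' @param signal a [CameraImage-class] (or bare yz matrix).
#' @param beamY the beam position, um.
#' @param det a [DetectionSpec-class] in confocal-line mode.
#' @param grid a [GridSpec-class] (needed for bare matrices).
#' @return A [CameraImage-class] with the mask applied.
#' @export
applySlit <- function(signal, beamY, det, grid = NULL) {
    stopIfNot(det@mode == "confocal-line",
              "applySlit: detection mode is '%s'; use widefieldImage()",
              det@mode)
    if (is(signal, "CameraImage")) {
        img <- signal@image; dy <- signal@dy; dz <- signal@dz
        prov <- signal@provenance
    } else {
        stopIfNot(!is.null(grid), "applySlit: 'grid' needed for matrix input")
        img <- signal; dy <- grid@dy; dz <- grid@dz; prov <- list()
    }
    ys <- (seq_len(nrow(img)) - (nrow(img) + 1) / 2) * dy
    keep <- abs(ys - beamY) <= det@slitWidth / 2
    img[!keep, ] <- 0
    prov$mode <- "confocal-line"; prov$beamY <- beamY
    prov$slitWidth <- det@slitWidth
    new("CameraImage", image = img, dy = dy, dz = dz, provenance = prov)
}
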