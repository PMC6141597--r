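## Internal numeric helpers.

## FFT sample frequencies (cycles per unit), numpy-fftfreq ordering.
fftFreq <- function(n, d) {
    k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
    k / (n * d)
}

## Periodic shift of the columns (y axis) of a matrix by `shift` entries.
rollCols <- function(m, shift) {
    n <- ncol(m)
    s <- ((shift %% n) + n) %% n
    if (s == 0) return(m)
    m[, c((n - s + 1):n, 1:(n - s)), drop = FALSE]
}

## Periodic shift of the rows (y axis of a yz image) by `shift` entries.
rollRows <- function(m, shift) {
    n <- nrow(m)
    s <- ((shift %% n) + n) %% n
    if (s == 0) return(m)
    m[c((n - s + 1):n, 1:(n - s)), , drop = FALSE]
}

## Normalized 1D Gaussian kernel sampled on the pixel grid.
gaussianKernel1D <- function(sigma, pitch, radiusSigmas = 4) {
    if (sigma <= 0) return(1)
    r <- max(1L, ceiling(radiusSigmas * sigma / pitch))
    x <- (-r:r) * pitch
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

## Separable 2D convolution with "same" extent and replicated edges,
## used for the camera lateral blur (kernels are narrow).
convolveSame1D <- function(x, kernel) {
    n <- length(x)
    if (length(kernel) == 1) return(x * kernel)
    r <- (length(kernel) - 1) / 2
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    stats::filter(xp, kernel, sides = 2)[(r + 1):(r + n)]
}

blurSeparable <- function(img, kernelRow, kernelCol) {
    if (length(kernelRow) > 1) img <- apply(img, 2, convolveSame1D, kernelRow)
    if (length(kernelCol) > 1)
        img <- t(apply(img, 1, convolveSame1D, kernelCol))
    img
}

## Centred moving average (window ~w) with symmetric, edge-shrinking
## windows: window asymmetry would bias slope fits on exponential profiles.
movingAverage <- function(x, w) {
    if (w <= 1) return(x)
    n <- length(x)
    cs <- cumsum(c(0, x))
    half <- pmin(floor((w - 1) / 2), seq_len(n) - 1, n - seq_len(n))
    lo <- seq_len(n) - half
    hi <- seq_len(n) + half
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## Indices of the `w` voxel centres nearest to coordinate `target`.
nearestIndices <- function(coords, target, w) {
    ord <- order(abs(coords - target), coords)
    sort(ord[seq_len(min(w, length(coords)))])
}

## Evaluate with a temporarily-seeded RNG, restoring the caller's state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

stopIfNot <- function(ok, ...) if (!ok) stop(sprintf(...), call. = FALSE)
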