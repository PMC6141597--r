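## Closed-form elliptical Gaussian beam geometry and the derived design
## quantities used to choose illumination parameters.

#' Gaussian beam waist from numerical aperture
#'
#' The 1/e^2 intensity radius at focus, \eqn{\omega_0 = \lambda / (\pi NA)}.
#' The vacuum wavelength is used, matching the standard design convention for
#' quoting light-sheet NA.
#'
#' @param na numerical aperture (> 0); vectorized.
#' @param wavelength vacuum wavelength, um.
#' @return Waist radius in um.
#' @examples
#' beamWaist(0.06, 0.660)   # 3.50 um
#' beamWaist(0.18, 0.660)   # 1.17 um
#' @export
beamWaist <- function(na, wavelength) {
    stopIfNot(all(is.finite(na)) && all(na > 0),
              "beamWaist: 'na' must be positive")
    stopIfNot(all(is.finite(wavelength)) && all(wavelength > 0),
              "beamWaist: 'wavelength' must be positive")
    wavelength / (pi * na)
}

#' Rayleigh range from numerical aperture
#'
#' \eqn{z_R = \pi \omega_0^2 / \lambda} with \eqn{\omega_0} from
#' [beamWaist()]. The confocal parameter (usable depth of focus) is twice
#' this value.
#'
#' @inheritParams beamWaist
#' @return Rayleigh range in um.
#' @examples
#' rayleighRange(0.06, 0.660)       # 58.4 um; confocal parameter ~117 um
#' @export
rayleighRange <- function(na, wavelength) {
    w0 <- beamWaist(na, wavelength)
    pi * w0^2 / wavelength
}

#' Gaussian beam 1/e^2 radius at an axial offset
#'
#' \eqn{\omega(z) = \omega_0 \sqrt{1 + (z / z_R)^2}}; even in z and minimal
#' at the waist, reaching \eqn{\sqrt{2}\,\omega_0} at \eqn{z = \pm z_R}.
#'
#' @param z axial offset from the waist, um; vectorized.
#' @inheritParams beamWaist
#' @return Beam radius in um.
#' @export
beamRadius <- function(z, na, wavelength) {
    w0 <- beamWaist(na, wavelength)
    zR <- rayleighRange(na, wavelength)
    w0 * sqrt(1 + (z / zR)^2)
}

#' Elliptical Gaussian beam intensity
#'
#' The normalized transverse intensity
#' \deqn{I(x, y, z) = \frac{2}{\pi \omega_x \omega_y}
#'   \exp\!\left[-2\left(\frac{x^2}{\omega_x^2} +
#'   \frac{y^2}{\omega_y^2}\right)\right]}
#' with \eqn{\omega_x, \omega_y} from [beamRadius()] evaluated at z (the x-
#' and y-waists are co-located at z = 0). The transverse integral is 1 at
#' every z.
#'
#' @param x,y,z coordinates in um (vectorized, recycled together).
#' @param beam a [BeamSpec-class] with \code{naY > 0}.
#' @return Intensity in um^-2.
#' @examples
#' b <- BeamSpec(0.06, 0.18)
#' beamIntensity(0, 0, 0, b)
#' @export
beamIntensity <- function(x, y, z, beam) {
    validObject(beam)
    stopIfNot(beam@naY > 0,
              "beamIntensity: closed form needs naY > 0 (focused in y)")
    wx <- beamRadius(z, beam@naX, beam@wavelength)
    wy <- beamRadius(z, beam@naY, beam@wavelength)
    2 / (pi * wx * wy) * exp(-2 * (x^2 / wx^2 + y^2 / wy^2))
}

#' Equivalent pivot half-angle for an in-sheet NA
#'
#' The marginal-ray half-angle \eqn{\arcsin(NA)} in degrees. A sheet pivoted
#' over this half-range delivers, after time averaging, the same in-plane
#' angular diversity as a static beam of the given NA_y; e.g. NA_y = 0.18
#' corresponds to a ~10 degree pivot.
#'
#' @param na in-sheet numerical aperture, 0 <= na < 1.
#' @return Half-angle in degrees.
#' @examples
#' pivotHalfAngle(0.18)   # ~10.4 deg
#' @export
pivotHalfAngle <- function(na) {
    stopIfNot(all(is.finite(na)) && all(na >= 0) && all(na < 1),
              "pivotHalfAngle: 'na' must lie in [0, 1)")
    asin(na) * 180 / pi
}

#' Confocal slit width rule
#'
#' The rolling-shutter slit is conventionally sized to 1.5x the beam diameter
#' at the Rayleigh range of the reference (circular DSLM) beam:
#' \eqn{\omega_{slit} = factor \cdot \sqrt{2}\,\omega_{0,y}}. Acquisition
#' scenarios may override this with an explicit slit width; the scenario
#' default used throughout the shipped presets is the fixed 20-um slit.
#'
#' @param naYRef reference in-sheet NA (the circular-beam NA_y).
#' @param wavelength vacuum wavelength, um.
#' @param factor slit oversize factor (default 1.5).
#' @return Slit width in um.
#' @examples
#' slitWidthRule(0.06, 0.660)   # 7.43 um
#' @export
slitWidthRule <- function(naYRef, wavelength, factor = 1.5) {
    stopIfNot(all(is.finite(factor)) && all(factor >= 0),
              "slitWidthRule: 'factor' must be non-negative")
    factor * sqrt(2) * beamWaist(naYRef, wavelength)
}
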