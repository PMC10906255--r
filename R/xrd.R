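# Bragg d-spacing from a low-angle diffraction peak.

#' Bragg spacing of a diffraction peak
#'
#' d = order x wavelength / (2 sin(theta)) with theta = two_theta / 2, the
#' lattice (here mesopore) repeat distance behind a low-angle XRD peak.
#' The default wavelength is Cu K-alpha, 0.15406 nm, the standard lab
#' source for low-angle measurements.
#'
#' @param two_theta Diffraction angle 2-theta in degrees, in (0, 180).
#' @param wavelength Wavelength in nm (default Cu K-alpha, 0.15406 nm).
#' @param order Diffraction order (integer >= 1).
#' @return d-spacing in nm.
#' @examples
#' bragg_spacing(0.46) # low-angle mesopore peak -> ~19 nm
#' @export
bragg_spacing <- function(two_theta, wavelength = 0.15406, order = 1) {
  stopifnot(wavelength > 0, order >= 1, order == round(order))
  if (any(two_theta <= 0) || any(two_theta >= 180)) {
    stop("two_theta must lie strictly between 0 and 180 degrees")
  }
  theta <- two_theta / 2 * pi / 180
  order * wavelength / (2 * sin(theta))
}
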