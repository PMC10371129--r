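# Surface-wave dispersion relations and their inversions.
#
# A focused ultrasound push excites a standing surface wave in the well; its
# resonant wavenumber k is fixed by the well radius and the resonant mode
# (k = z/a, see WellGeometry). In the liquid regime the restoring force is
# surface tension and the wave is capillary: f = (1/2pi) sqrt(sigma k^3 /
# rho). Once the sample has gelled the wave is a Rayleigh wave on an elastic
# half-space: f = (1/2pi) sqrt(G k^2 / rho). Measuring f therefore yields
# sigma before clotting and G after. Regime selection is the caller's
# responsibility (liquid before clotting starts, solid after it ends); the
# crossover regime has no closed-form dispersion here.

.checkPositive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      stop("'", nm, "' must be positive and finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Capillary-wave resonant frequency of a liquid surface
#'
#' Dispersion relation of a capillary (surface-tension-driven) wave:
#' `f = (1/2pi) * sqrt(sigma * k^3 / rho)`.
#'
#' @param sigma surface tension, N/m
#' @param rho mass density, kg/m^3
#' @param k resonant wavenumber, 1/m (see [wellGeometry()])
#' @return resonant frequency in Hz; vectorised over its arguments
#' @seealso [invertToSurfaceTension()], [rayleighFrequency()]
#' @export
#' @examples
#' k <- wavenumber(wellGeometry())
#' capillaryFrequency(0.072, 1000, k)  # ~54.7 Hz for a water-like surface
capillaryFrequency <- function(sigma, rho, k) {
  .checkPositive(sigma = sigma, rho = rho, k = k)
  sqrt(sigma * k^3 / rho) / (2 * pi)
}

#' Rayleigh-wave resonant frequency of a soft solid surface
#'
#' Dispersion relation of a Rayleigh (elastic) surface wave:
#' `f = (1/2pi) * sqrt(G * k^2 / rho) = (k/2pi) * sqrt(G/rho)`.
#'
#' @param G shear modulus, Pa
#' @inheritParams capillaryFrequency
#' @return resonant frequency in Hz; vectorised
#' @seealso [invertToShearModulus()], [capillaryFrequency()]
#' @export
#' @examples
#' k <- wavenumber(wellGeometry())
#' rayleighFrequency(1000, 1000, k)  # ~187.6 Hz for a 1 kPa clot
rayleighFrequency <- function(G, rho, k) {
  .checkPositive(G = G, rho = rho, k = k)
  (k / (2 * pi)) * sqrt(G / rho)
}

#' Invert a capillary-wave frequency to surface tension
#'
#' Algebraic inversion of the capillary dispersion relation:
#' `sigma = (2 pi f)^2 * rho / k^3`. Valid for the liquid regime (before
#' clotting starts).
#'
#' @param f measured resonant frequency, Hz
#' @inheritParams capillaryFrequency
#' @return surface tension in N/m; vectorised
#' @export
#' @examples
#' k <- wavenumber(wellGeometry())
#' invertToSurfaceTension(capillaryFrequency(0.072, 1000, k), 1000, k)
invertToSurfaceTension <- function(f, rho, k) {
  .checkPositive(f = f, rho = rho, k = k)
  (2 * pi * f)^2 * rho / k^3
}

#' Invert a Rayleigh-wave frequency to shear modulus
#'
#' Algebraic inversion of the Rayleigh dispersion relation:
#' `G = rho * (2 pi f / k)^2`. Valid for the solid regime (after clotting
#' has completed).
#'
#' @param f measured resonant frequency, Hz
#' @inheritParams capillaryFrequency
#' @return shear modulus in Pa; vectorised
#' @export
#' @examples
#' k <- wavenumber(wellGeometry())
#' invertToShearModulus(rayleighFrequency(1000, 1000, k), 1000, k)
invertToShearModulus <- function(f, rho, k) {
  .checkPositive(f = f, rho = rho, k = k)
  rho * (2 * pi * f / k)^2
}
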