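#' Faddeeva function w(z) for the upper half plane
#'
#' Computes the scaled complex complementary error function
#' \eqn{w(z) = e^{-z^2} \mathrm{erfc}(-iz)} using Weideman's rational
#' approximation, which is uniformly accurate for \eqn{\Im(z) \ge 0} --
#' the regime needed for Voigt lineshapes (Lorentzian half-width
#' \eqn{\gamma \ge 0}).
#'
#' @param z complex vector with non-negative imaginary part.
#' @param n order of the rational approximation (default 32, giving
#'   relative accuracy far beyond linewidth-fitting needs).
#' @return complex vector, same length as `z`.
#' @keywords internal
faddeeva_w <- function(z, n = 32L) {
  stopifnot(is.numeric(n), n >= 8)
  if (any(Im(z) < -1e-12)) {
    stop("faddeeva_w() is only valid for Im(z) >= 0")
  }
  m  <- 2L * n
  m2 <- 2L * m
  k  <- seq.int(-m + 1L, m - 1L)
  L  <- sqrt(n / sqrt(2))
  theta <- k * pi / m
  t  <- L * tan(theta / 2)
  f  <- exp(-t^2) * (L^2 + t^2)
  f  <- c(0, f)
  f  <- c(f[(m + 1L):m2], f[1:m])     # fftshift for the even-length grid
  a  <- Re(stats::fft(f)) / m2
  a  <- rev(a[2:(n + 1L)])            # polynomial coefficients, descending
  Z  <- (L + 1i * z) / (L - 1i * z)
  p  <- rep(0 + 0i, length(z))        # Horner evaluation of the polynomial
  for (coef in a) p <- p * Z + coef
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

#' Construct a Voigt peak description
#'
#' A Voigt profile is the convolution of a Gaussian (standard deviation
#' `sigma_g`) and a Lorentzian (half-width at half maximum `gamma_l`),
#' the standard model for NMR lineshapes. Widths are in ppm, `area` in
#' intensity x ppm.
#'
#' @param center peak position (ppm).
#' @param sigma_g Gaussian standard deviation (ppm), `>= 0`.
#' @param gamma_l Lorentzian half-width at half maximum (ppm), `>= 0`.
#' @param area integrated intensity (intensity x ppm).
#' @return an object of class `voigt_peak`.
#' @export
#' @examples
#' pk <- voigt_peak(center = 3.6, sigma_g = 0.0005, gamma_l = 0.001, area = 2)
voigt_peak <- function(center, sigma_g, gamma_l, area) {
  stopifnot(is.finite(center), is.finite(area))
  if (sigma_g < 0 || gamma_l < 0) stop("Voigt widths must be non-negative")
  if (sigma_g == 0 && gamma_l == 0) {
    stop("Voigt peak needs at least one non-zero width")
  }
  structure(list(center = center, sigma_g = sigma_g,
                 gamma_l = gamma_l, area = area),
            class = "voigt_peak")
}

#' Evaluate a Voigt profile on a chemical-shift grid
#'
#' Evaluates the Gaussian (x) Lorentzian convolution scaled so that the
#' integral over the whole real line equals `peak$area`. Pure-Gaussian and
#' pure-Lorentzian limits are handled in closed form.
#'
#' @param x ppm grid (any order, need not be uniform).
#' @param peak a [voigt_peak()].
#' @return numeric vector of intensities, same length as `x`.
#' @export
voigt_profile <- function(x, peak) {
  if (length(x) < 1) stop("empty evaluation grid")
  if (!inherits(peak, "voigt_peak")) peak <- do.call(voigt_peak, peak)
  dx <- x - peak$center
  s  <- peak$sigma_g
  g  <- peak$gamma_l
  if (s <= 0) {                        # pure Lorentzian
    return(peak$area * g / (pi * (dx^2 + g^2)))
  }
  if (g <= 0) {                        # pure Gaussian
    return(peak$area * exp(-dx^2 / (2 * s^2)) / (s * sqrt(2 * pi)))
  }
  z <- (dx + 1i * g) / (s * sqrt(2))
  peak$area * Re(faddeeva_w(z)) / (s * sqrt(2 * pi))
}

#' Apex height of a Voigt peak
#'
#' Intensity of the profile at its center; used to translate configured
#' signal-to-noise ratios into noise standard deviations.
#'
#' @param peak a [voigt_peak()].
#' @return scalar intensity.
#' @export
voigt_height <- function(peak) {
  voigt_profile(peak$center, peak)
}

#' Approximate Voigt FWHM (ppm)
#'
#' Olivero--Longbothum approximation, accurate to ~0.02%; used for
#' default template widths and fit-region sizing.
#'
#' @param sigma_g Gaussian sd (ppm).
#' @param gamma_l Lorentzian HWHM (ppm).
#' @return scalar FWHM in ppm.
#' @keywords internal
voigt_fwhm <- function(sigma_g, gamma_l) {
  fg <- 2 * sqrt(2 * log(2)) * sigma_g
  fl <- 2 * gamma_l
  0.5346 * fl + sqrt(0.2166 * fl^2 + fg^2)
}

#' Voigt width components for a target FWHM
#'
#' The package-wide lineshape convention: one third of the FWHM is
#' assigned to the Lorentzian component (HWHM `gamma_l = fwhm / 3`) and
#' the Gaussian share follows from inverting the Olivero--Longbothum
#' FWHM relation. Both the synthetic generator and the deconvolution
#' templates use this split, so fitted and generated lineshapes share
#' one mix.
#'
#' @param fwhm full width at half maximum (any unit; outputs share it).
#' @return list with `sigma_g` (Gaussian sd) and `gamma_l`
#'   (Lorentzian HWHM).
#' @export
voigt_widths_from_fwhm <- function(fwhm) {
  gl <- fwhm / 3
  fl <- 2 * gl
  fg2 <- (fwhm - 0.5346 * fl)^2 - 0.2166 * fl^2
  sg <- if (fg2 > 0) sqrt(fg2) / (2 * sqrt(2 * log(2))) else 0
  list(sigma_g = sg, gamma_l = gl)
}
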