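# Inelastic in-water sources: chlorophyll-a fluorescence with
# photochemical/non-photochemical quenching, plus simplified water Raman
# scattering and dissolved organic matter fluorescence.

#' Quenching parameters for the fluorescence quantum yield
#'
#' Defaults are the study values: qI = 0.35, Ek = 55 and ET = 634
#' micromol quanta m-2 s-1, minimum/maximum yields 0.03/0.09.
#'
#' @param qI reaction-center quenching factor, 0-1
#' @param Ek light-saturation parameter of photochemical quenching
#'   [umol quanta m-2 s-1]
#' @param ET light-saturation parameter of energy-dependent
#'   (non-photochemical) quenching [umol quanta m-2 s-1]
#' @param phi_min,phi_max minimum and maximum quantum yields
#' @return object of class `quenching_params`
#' @export
quenching_params <- function(qI = 0.35, Ek = 55, ET = 634,
                             phi_min = 0.03, phi_max = 0.09) {
  stopifnot(qI >= 0, qI <= 1, Ek > 0, ET > 0, phi_min >= 0,
            phi_min <= phi_max)
  structure(list(qI = qI, Ek = Ek, ET = ET, phi_min = phi_min,
                 phi_max = phi_max), class = "quenching_params")
}

#' Fluorescence emission specification
#'
#' Gaussian emission line (peak 685 nm, standard deviation 10.6 nm) excited
#' within 370-690 nm.
#'
#' @param lambda0 wavelength of maximum emission [nm]
#' @param sigma Gaussian standard deviation [nm]
#' @param window excitation window [nm], length 2
#' @return object of class `emission_spec`
#' @export
emission_spec <- function(lambda0 = 685, sigma = 10.6,
                          window = c(370, 690)) {
  stopifnot(sigma > 0, length(window) == 2, window[1] < window[2])
  structure(list(lambda0 = lambda0, sigma = sigma, window = window),
            class = "emission_spec")
}

#' Instantaneous photosynthetically available radiation
#'
#' \eqn{IPAR = \int E_o(\lambda)\,\lambda/(hc)\,d\lambda} over the window,
#' converted to micromole quanta. Trapezoid quadrature on the supplied grid
#' restricted to the window.
#'
#' @param Eo scalar irradiance spectrum [W m-2 nm-1]; may be a matrix with
#'   one row per depth
#' @param wavelength wavelengths of the spectrum [nm]
#' @param window integration window [nm]
#' @return IPAR [umol quanta m-2 s-1]; a vector if `Eo` is a matrix
#' @export
ipar <- function(Eo, wavelength, window = c(370, 690)) {
  keep <- wavelength >= window[1] & wavelength <= window[2]
  if (sum(keep) < 2) stop("empty IPAR window on the supplied grid")
  wl <- wavelength[keep]
  wts <- trapz_weights(wl)
  conv <- wl * 1e-9 / .hc / .avogadro * 1e6
  if (is.matrix(Eo)) {
    if (any(Eo < 0)) stop("Eo must be non-negative")
    as.vector(Eo[, keep, drop = FALSE] %*% (wts * conv))
  } else {
    if (any(Eo < 0)) stop("Eo must be non-negative")
    sum(Eo[keep] * wts * conv)
  }
}

#' Quenching-dependent fluorescence quantum yield
#'
#' \eqn{\Phi_C = q_I e^{-IPAR/E_T}\left(\Phi_{min} e^{-IPAR/E_k} +
#' \Phi_{max}(1 - e^{-IPAR/E_k})\right)}: the bracket is photochemical
#' quenching (saturating with Ek), the leading exponential is
#' non-photochemical quenching (suppression at high light).
#'
#' @param ipar_value IPAR [umol quanta m-2 s-1], >= 0; vectorized
#' @param params a [quenching_params()]
#' @return quantum yield, within [0, qI * phi_max]
#' @export
quantum_yield <- function(ipar_value, params = quenching_params()) {
  stopifnot(all(ipar_value >= 0))
  ek <- exp(-ipar_value / params$Ek)
  params$qI * exp(-ipar_value / params$ET) *
    (params$phi_min * ek + params$phi_max * (1 - ek))
}

#' Fluorescence scattering coefficient
#'
#' \eqn{b_C(\lambda, \lambda_e) = a_p \Phi_C \frac{1}{\sqrt{2\pi}\sigma_C}
#' \exp\!\left(-\frac{(\lambda-\lambda_{C,0})^2}{2\sigma_C^2}\right)
#' \frac{\lambda_e}{\lambda}} for excitation inside the window, zero
#' outside.
#'
#' @param lambda emission wavelength [nm]
#' @param lambda_e excitation wavelength(s) [nm]
#' @param a_p phytoplankton absorption at the excitation wavelength [m-1]
#' @param phi fluorescence quantum yield
#' @param spec an [emission_spec()]
#' @return bC [m-1 nm-1]
#' @export
fluorescence_b <- function(lambda, lambda_e, a_p, phi,
                           spec = emission_spec()) {
  stopifnot(all(a_p >= 0), all(phi >= 0))
  gaus <- exp(-(lambda - spec$lambda0)^2 / (2 * spec$sigma^2)) /
    (sqrt(2 * pi) * spec$sigma)
  inside <- lambda_e >= spec$window[1] & lambda_e <= spec$window[2]
  ifelse(inside, a_p * phi * gaus * lambda_e / lambda, 0)
}

#' Isotropic chlorophyll fluorescence volume source
#'
#' \eqn{S_C(z, \lambda) = \frac{1}{4\pi}\int b_C(z, \lambda, \lambda_e)
#' E_o(z, \lambda_e)\,d\lambda_e} by trapezoid quadrature over the
#' excitation grid.
#'
#' @param lambda emission wavelength [nm] (scalar)
#' @param Eo excitation scalar irradiance, matrix [depth x excitation
#'   wavelength] [W m-2 nm-1]
#' @param lambda_e excitation wavelength grid [nm]
#' @param a_p phytoplankton absorption on the excitation grid [m-1]
#' @param phi quantum yield per depth (vector, recycled over wavelength)
#' @param spec an [emission_spec()]
#' @return source profile S_C(z) [W m-3 nm-1 sr-1]
#' @export
fluorescence_source <- function(lambda, Eo, lambda_e, a_p, phi,
                                spec = emission_spec()) {
  if (!is.matrix(Eo)) Eo <- matrix(Eo, nrow = 1)
  if (ncol(Eo) != length(lambda_e)) {
    stop("excitation grid mismatch between Eo and lambda_e")
  }
  if (length(a_p) != length(lambda_e)) {
    stop("a_p must be given on the excitation grid")
  }
  if (length(phi) != nrow(Eo)) stop("phi must be given per depth")
  wts <- trapz_weights(lambda_e)
  bc_unit <- fluorescence_b(lambda, lambda_e, a_p, 1, spec)
  as.vector(phi * (Eo %*% (wts * bc_unit))) / (4 * pi)
}

#' Raman scattering parameters
#'
#' Simplified single-Gaussian wavenumber-redistribution model: Raman
#' scattering coefficient \eqn{b_R(\lambda_e) = b_{R,488}
#' (488/\lambda_e)^{5.3}} and a normalized Gaussian shift distribution
#' centered at 3350 cm-1 with width 150 cm-1.
#'
#' @param bR488 Raman scattering coefficient at 488 nm [m-1]
#' @param slope spectral exponent of bR
#' @param shift center of the wavenumber shift [cm-1]
#' @param width Gaussian standard deviation of the shift [cm-1]
#' @param enabled logical
#' @return list of class `raman_params`
#' @export
raman_params <- function(bR488 = 2.6e-4, slope = 5.3, shift = 3350,
                         width = 150, enabled = TRUE) {
  structure(list(bR488 = bR488, slope = slope, shift = shift,
                 width = width, enabled = isTRUE(enabled)),
            class = "raman_params")
}

# Wavenumber-shift redistribution density in emission wavelength for fixed
# excitation: f(lambda | lambda_e) [nm-1], normalized over lambda.
raman_redistribution <- function(lambda, lambda_e, params = raman_params()) {
  nu <- 1e7 * (1 / lambda_e - 1 / lambda)      # shift [cm-1], positive
  stats::dnorm(nu, params$shift, params$width) * 1e7 / lambda^2
}

#' Water Raman volume source
#'
#' \eqn{S_R(z,\lambda) = \frac{1}{4\pi}\int b_R(\lambda_e)
#' f(\lambda_e \to \lambda)\,E_o(z, \lambda_e)\,d\lambda_e}.
#'
#' @inheritParams fluorescence_source
#' @param params a [raman_params()]
#' @return source profile S_R(z) [W m-3 nm-1 sr-1] (zero when disabled)
#' @export
raman_source <- function(lambda, Eo, lambda_e, params = raman_params()) {
  if (!is.matrix(Eo)) Eo <- matrix(Eo, nrow = 1)
  if (!params$enabled) return(numeric(nrow(Eo)))
  if (ncol(Eo) != length(lambda_e)) {
    stop("excitation grid mismatch between Eo and lambda_e")
  }
  wts <- trapz_weights(lambda_e)
  bR <- params$bR488 * (488 / lambda_e)^params$slope
  f <- raman_redistribution(lambda, lambda_e, params)
  as.vector(Eo %*% (wts * bR * f)) / (4 * pi)
}

#' Dissolved organic matter fluorescence volume source
#'
#' \eqn{S_Y(z,\lambda) = \frac{1}{4\pi}\int a_y(\lambda_e)\,\eta\,
#' g(\lambda_e,\lambda)\,E_o\,d\lambda_e} with scalar efficiency `eta` and a
#' normalized Gaussian emission kernel Stokes-shifted from the excitation
#' wavelength. Disabled by default (eta = 0).
#'
#' @inheritParams fluorescence_source
#' @param a_y CDOM absorption on the excitation grid [m-1]
#' @param eta fluorescence efficiency (photon basis), >= 0; 0 disables
#' @param stokes_shift emission kernel offset from the excitation
#'   wavelength [nm]
#' @param width emission kernel standard deviation [nm]
#' @return source profile S_Y(z) [W m-3 nm-1 sr-1]
#' @export
fdom_source <- function(lambda, Eo, lambda_e, a_y, eta = 0,
                        stokes_shift = 50, width = 30) {
  if (!is.matrix(Eo)) Eo <- matrix(Eo, nrow = 1)
  if (eta <= 0) return(numeric(nrow(Eo)))
  if (ncol(Eo) != length(lambda_e)) {
    stop("excitation grid mismatch between Eo and lambda_e")
  }
  if (length(a_y) != length(lambda_e)) {
    stop("a_y must be given on the excitation grid")
  }
  wts <- trapz_weights(lambda_e)
  g <- stats::dnorm(lambda, lambda_e + stokes_shift, width)
  # photon-conserving wavelength ratio, as for chlorophyll fluorescence
  as.vector(Eo %*% (wts * a_y * eta * g * lambda_e / lambda)) / (4 * pi)
}
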