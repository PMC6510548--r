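# Layered scalar atmosphere: Rayleigh scattering, maritime-like aerosol,
# parameterized gas band transmittance.

# Rayleigh shape factor gamma = delta/(2-delta) at depolarization 0.0284.
.depol_default <- 0.0284

#' Rayleigh column optical depth
#'
#' Standard column fit \eqn{\tau_R = 0.008569\,\lambda^{-4}(1 +
#' 0.0113\lambda^{-2} + 0.00013\lambda^{-4})} with wavelength in micrometers.
#'
#' @param wavelength wavelengths [nm], 350-800
#' @return optical depth (dimensionless)
#' @export
rayleigh_optical_depth <- function(wavelength) {
  if (any(wavelength < 350 | wavelength > 800)) {
    stop("wavelength outside 350-800 nm")
  }
  lu <- wavelength / 1000
  0.008569 * lu^-4 * (1 + 0.0113 * lu^-2 + 0.00013 * lu^-4)
}

#' Scalar Rayleigh phase function with depolarization
#'
#' \eqn{P(\theta) = \frac{3}{4(1+2\gamma)}[(1+3\gamma) +
#' (1-\gamma)\cos^2\theta]} with \eqn{\gamma = \delta/(2-\delta)},
#' normalized to 1 over \eqn{4\pi}.
#'
#' @param angle scattering angles [rad], 0 to pi
#' @param depolarization depolarization factor delta
#' @return phase-function values
#' @export
rayleigh_phase <- function(angle, depolarization = .depol_default) {
  stopifnot(all(angle >= 0), all(angle <= pi + 1e-12))
  g <- depolarization / (2 - depolarization)
  phase_exact(cos(angle), 0, 1, g, 0, 0)
}

#' Atmosphere state
#'
#' Aerosol loading and model parameters plus layering and the gas-absorption
#' switch. Aerosol single-scattering properties default to a maritime-like
#' Henyey-Greenstein description (g = 0.75, single-scattering albedo 0.98,
#' Angstrom exponent 0.3).
#'
#' @param tau_a550 aerosol optical depth at 550 nm
#' @param angstrom Angstrom exponent of the aerosol optical depth
#' @param g aerosol asymmetry parameter
#' @param ssa aerosol single-scattering albedo
#' @param scale_height aerosol exponential scale height [km]
#' @param n_layers number of atmospheric layers
#' @param gas_absorption enable the packaged gas band transmittances
#' @return object of class `atmosphere_state`
#' @export
atmosphere_state <- function(tau_a550 = 0.1, angstrom = 0.3, g = 0.75,
                             ssa = 0.98, scale_height = 2, n_layers = 10,
                             gas_absorption = TRUE) {
  stopifnot(tau_a550 >= 0, g > -1, g < 1, ssa > 0, ssa <= 1, n_layers >= 1,
            scale_height > 0)
  structure(list(tau_a550 = tau_a550, angstrom = angstrom, g = g, ssa = ssa,
                 scale_height = scale_height, n_layers = n_layers,
                 gas_absorption = isTRUE(gas_absorption)),
            class = "atmosphere_state")
}

#' Aerosol optical depth
#'
#' Angstrom power law referenced at 550 nm.
#'
#' @param wavelength wavelengths [nm]
#' @param state an [atmosphere_state()]
#' @return optical depth
#' @export
aerosol_optical_depth <- function(wavelength, state) {
  state$tau_a550 * (550 / wavelength)^state$angstrom
}

#' Column gas transmittance
#'
#' Product of the packaged band-averaged absorber transmittances (oxygen B/A
#' bands, water-vapor bands, ozone Chappuis) raised to the air mass. Returns
#' 1 everywhere when disabled.
#'
#' @param wavelength wavelengths [nm], 350-800
#' @param airmass relative air mass (>= 1)
#' @param enabled gas-absorption flag
#' @return transmittance in (0, 1]
#' @export
gas_transmittance <- function(wavelength, airmass = 1, enabled = TRUE) {
  stopifnot(all(airmass >= 1))
  if (!enabled) return(rep(1, length(wavelength)))
  tab <- fixture_table("gas_transmittance")
  t1 <- interp_strict(tab$wavelength, tab$T_o2 * tab$T_h2o * tab$T_o3,
                      wavelength, "gas transmittance table")
  t1^airmass
}

# Vertical gas absorption optical depth (air mass 1).
gas_optical_depth <- function(wavelength, enabled = TRUE) {
  -log(gas_transmittance(wavelength, 1, enabled))
}

#' Build the atmospheric part of a layer stack
#'
#' Layered optical thickness, single-scattering albedo and phase-function
#' mixture for one wavelength. The molecular column follows an 8 km
#' exponential profile, the aerosol the configured scale height; within a
#' layer the Rayleigh and aerosol phase functions are blended with
#' scattering-coefficient weights. Gas absorption is distributed with the
#' molecular profile.
#'
#' @param state an [atmosphere_state()]
#' @param wavelength a single wavelength [nm]
#' @return data.frame of layers (top first) with columns tau, omega, and
#'   phase mixture columns `w_iso`, `w_ray`, `gamma`, `w_hg`, `g`, plus
#'   medium = "air".
#' @export
build_atmosphere_stack <- function(state, wavelength) {
  stopifnot(length(wavelength) == 1)
  n <- state$n_layers
  # layer boundaries in altitude [km], top first
  z <- c(60, exp(seq(log(30), log(1), length.out = n - 1)), 0)
  col_frac <- function(h) {
    f <- exp(-z / h)
    diff(f) / (exp(-z[length(z)] / h) - exp(-z[1] / h))
  }
  f_ray <- col_frac(8)
  f_aer <- col_frac(state$scale_height)
  tau_ray <- rayleigh_optical_depth(wavelength) * f_ray
  tau_aer <- aerosol_optical_depth(wavelength, state) * f_aer
  tau_gas <- gas_optical_depth(wavelength, state$gas_absorption) * f_ray
  tau <- tau_ray + tau_aer + tau_gas
  b_scat <- tau_ray + state$ssa * tau_aer
  omega <- ifelse(tau > 0, b_scat / tau, 0)
  w_ray <- ifelse(b_scat > 0, tau_ray / b_scat, 1)
  gamma <- .depol_default / (2 - .depol_default)
  data.frame(tau = tau, omega = omega, medium = "air",
             w_iso = 0, w_ray = w_ray, gamma = gamma,
             w_hg = 1 - w_ray, g = state$g,
             dz = NA_real_, cext = NA_real_)
}
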