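# Bio-optical model of the three-component ocean: pure sea water, CDOM and
# chlorophyll-covariant particles.

# Phase-function shape constants.
# Pure-water (Rayleigh-like) phase function 1 + 0.835 cos^2(theta) expressed
# in the depolarized-Rayleigh family P ~ (1+3g) + (1-g) cos^2, g such that
# (1-g)/(1+3g) = 0.835.
.gamma_water <- (1 - 0.835) / (3 * 0.835 + 1)

#' Pure sea-water absorption coefficient
#'
#' Linear interpolation of the packaged pure-water absorption table
#' (350-750 nm).
#'
#' @param wavelength wavelengths [nm]
#' @return absorption [m-1]
#' @export
water_absorption <- function(wavelength) {
  tab <- fixture_table("water_absorption")
  interp_strict(tab$wavelength, tab$absorption, wavelength,
                "pure-water absorption table")
}

#' Pure sea-water scattering coefficient
#'
#' Power law \eqn{b_w(\lambda) = b_w(450)\,(450/\lambda)^{4.32}} with
#' reference value 0.00453 m-1 at 450 nm.
#'
#' @param wavelength wavelengths [nm], 350-750
#' @param b450 reference scattering at 450 nm [m-1]
#' @return scattering [m-1]
#' @export
water_scattering <- function(wavelength, b450 = 0.00453) {
  if (any(wavelength < 350 | wavelength > 750)) {
    stop("wavelength outside 350-750 nm")
  }
  b450 * (450 / wavelength)^4.32
}

#' CDOM absorption coefficient
#'
#' Exponential decay with slope 0.018 nm-1 referenced at 440 nm.
#'
#' @param wavelength wavelengths [nm]
#' @param a440 CDOM absorption at 440 nm [m-1]
#' @param slope spectral slope [nm-1]
#' @return absorption [m-1]
#' @export
cdom_absorption <- function(wavelength, a440, slope = 0.018) {
  stopifnot(a440 >= 0)
  a440 * exp(-slope * (wavelength - 440))
}

#' Phytoplankton absorption coefficient
#'
#' Chlorophyll-specific power law \eqn{a_p = A(\lambda)\,[Chla]^{E(\lambda)}}
#' with packaged coefficient tables (pigment packaging included in E < 1).
#'
#' @param wavelength wavelengths [nm], within the coefficient table (370-750)
#' @param chla chlorophyll-a concentration [mg m-3]
#' @return absorption [m-1]
#' @export
phytoplankton_absorption <- function(wavelength, chla) {
  stopifnot(chla >= 0)
  if (chla == 0) return(numeric(length(wavelength)) + 0)
  tab <- fixture_table("bricaud_ap")
  A <- interp_strict(tab$wavelength, tab$A, wavelength,
                     "phytoplankton coefficient table")
  E <- interp_strict(tab$wavelength, tab$E, wavelength,
                     "phytoplankton coefficient table")
  A * chla^E
}

#' Particle beam attenuation coefficient
#'
#' Power law for the chlorophyll-covariant particle extinction,
#' \eqn{c_p = c_{660}\,[Chla]^{0.57}\,(660/\lambda)^{\nu}} with defaults
#' c660 = 0.39 m-1 and spectral slope nu = 1.
#'
#' @param wavelength wavelengths [nm]
#' @param chla chlorophyll-a concentration [mg m-3]
#' @param c660 extinction at 660 nm for Chla = 1 [m-1]
#' @param nu spectral slope exponent
#' @return extinction [m-1]
#' @export
particle_extinction <- function(wavelength, chla, c660 = 0.39, nu = 1) {
  stopifnot(chla >= 0)
  c660 * chla^0.57 * (660 / wavelength)^nu
}

#' Ocean state
#'
#' Container for the water-column description used by the IOP assembly:
#' chlorophyll concentration, CDOM amplitude (default tied to the
#' phytoplankton absorption at 440 nm by a440 = 0.2 a_p(440)), depth grid and
#' particle backscattering ratio.
#'
#' @param chla chlorophyll-a concentration [mg m-3]
#' @param cdom_a440 CDOM absorption at 440 nm [m-1]; `NULL` ties it to chla
#' @param depth_grid strictly increasing depths [m] starting at 0, or `NULL`
#'   to let the simulator build one
#' @param bottom_depth bottom depth [m]; must be >= the last depth grid point
#' @param backscatter_ratio particle backscattering ratio (0-0.5)
#' @return object of class `ocean_state`
#' @export
ocean_state <- function(chla = 1, cdom_a440 = NULL, depth_grid = NULL,
                        bottom_depth = NULL, backscatter_ratio = 0.01) {
  stopifnot(chla >= 0, backscatter_ratio >= 0, backscatter_ratio <= 0.5)
  if (is.null(cdom_a440)) {
    cdom_a440 <- 0.2 * phytoplankton_absorption(440, chla)
  }
  stopifnot(cdom_a440 >= 0)
  if (!is.null(depth_grid)) {
    if (depth_grid[1] != 0 || any(diff(depth_grid) <= 0)) {
      stop("depth_grid must start at 0 and be strictly increasing")
    }
    if (is.null(bottom_depth)) bottom_depth <- max(depth_grid)
    if (bottom_depth < max(depth_grid)) {
      stop("bottom_depth must be at least the last depth grid point")
    }
  }
  if (!is.null(bottom_depth)) stopifnot(bottom_depth > 0)
  structure(list(chla = chla, cdom_a440 = cdom_a440,
                 depth_grid = depth_grid, bottom_depth = bottom_depth,
                 backscatter_ratio = backscatter_ratio),
            class = "ocean_state")
}

# Henyey-Greenstein backscattering ratio as a function of the asymmetry
# parameter g: fraction of scattered power into the backward hemisphere.
hg_backscatter_fraction <- function(g) {
  if (g == 0) return(0.5)
  (1 - g) / (2 * g) * ((1 + g) / sqrt(1 + g^2) - 1)
}

# Asymmetry parameter whose HG phase function matches a given backscattering
# ratio.
hg_g_for_backscatter <- function(bb_ratio) {
  stopifnot(bb_ratio > 0, bb_ratio <= 0.5)
  if (bb_ratio >= 0.5) return(0)
  stats::uniroot(function(g) hg_backscatter_fraction(g) - bb_ratio,
                 c(1e-6, 1 - 1e-9), tol = 1e-12)$root
}

# Legendre moments chi_l (chi_0 = 1) of the component phase functions.
# "ray" family: P(c) = 3/(4(1+2g)) ((1+3g) + (1-g) c^2).
phase_moments_components <- function(w_iso, w_ray, gamma, w_hg, g, lmax) {
  l <- 0:lmax
  chi <- w_hg * g^l
  chi[1] <- chi[1] + w_iso + w_ray
  if (lmax >= 2) chi[3] <- chi[3] + w_ray * (1 - gamma) / (10 * (1 + 2 * gamma))
  chi
}

# Closed-form phase function of a mixed layer at scattering-angle cosines c.
phase_exact <- function(cosang, w_iso, w_ray, gamma, w_hg, g) {
  p <- w_iso + w_ray * 3 / (4 * (1 + 2 * gamma)) *
    ((1 + 3 * gamma) + (1 - gamma) * cosang^2)
  if (w_hg > 0) {
    p <- p + w_hg * (1 - g^2) / (1 + g^2 - 2 * g * cosang)^1.5
  }
  p
}

#' Evaluate a mixed phase function
#'
#' Closed-form scalar phase function of a layer described by its mixture
#' weights (isotropic, Rayleigh-like with depolarization-type shape factor
#' `gamma`, Henyey-Greenstein with asymmetry `g`), normalized to 1 over
#' \eqn{4\pi}.
#'
#' @param angle scattering angles [rad]
#' @param phase list/row with fields `w_iso`, `w_ray`, `gamma`, `w_hg`, `g`
#' @return phase-function values (dimensionless, mean over solid angle = 1)
#' @export
phase_function <- function(angle, phase) {
  phase_exact(cos(angle), phase$w_iso, phase$w_ray, phase$gamma,
              phase$w_hg, phase$g)
}

#' Assemble spectrally resolved water-column IOPs
#'
#' Total absorption, scattering and extinction plus the mixed phase-function
#' description for the three-component ocean on a wavelength grid. The water
#' column is homogeneous (constant chlorophyll with depth); per-component
#' coefficients are returned so the fluorescence source can reuse
#' \eqn{a_p(\lambda)}.
#'
#' Particle scattering is \eqn{b_p = c_p - a_p}, clamped at zero (with a
#' warning) if a parameter override makes it negative. The mixture phase
#' function weights the pure-water Rayleigh-like shape and the particle
#' Henyey-Greenstein shape (asymmetry matched to the configured
#' backscattering ratio) by their scattering coefficients.
#'
#' @param state an [ocean_state()]
#' @param wavelength wavelength grid [nm]
#' @param c660,nu particle extinction parameters, see [particle_extinction()]
#' @return list of class `ocean_iop` with vectors on the wavelength grid:
#'   `a`, `b`, `c`, components `a_w`, `a_y`, `a_p`, `b_w`, `b_p`, phase
#'   mixture columns and the particle asymmetry parameter `g_p`.
#' @export
assemble_iop_profile <- function(state, wavelength, c660 = 0.39, nu = 1) {
  stopifnot(inherits(state, "ocean_state"))
  a_w <- water_absorption(wavelength)
  b_w <- water_scattering(wavelength)
  a_y <- cdom_absorption(wavelength, state$cdom_a440)
  a_p <- phytoplankton_absorption(wavelength, state$chla)
  c_p <- particle_extinction(wavelength, state$chla, c660 = c660, nu = nu)
  b_p <- c_p - a_p
  if (any(b_p < 0) && state$chla > 0) {
    warning("particle scattering c_p - a_p < 0 at some wavelengths; ",
            "clamped to zero")
  }
  b_p <- pmax(b_p, 0)
  a <- a_w + a_y + a_p
  b <- b_w + b_p
  g_p <- hg_g_for_backscatter(max(state$backscatter_ratio, 1e-6))
  w_ray <- ifelse(b > 0, b_w / b, 1)
  structure(list(wavelength = wavelength, a = a, b = b, c = a + b,
                 a_w = a_w, a_y = a_y, a_p = a_p, b_w = b_w, b_p = b_p,
                 w_iso = rep(0, length(wavelength)),
                 w_ray = w_ray, gamma = rep(.gamma_water, length(wavelength)),
                 w_hg = 1 - w_ray, g_p = g_p,
                 backscatter_ratio = state$backscatter_ratio,
                 state = state),
            class = "ocean_iop")
}

#' Legendre moments of the mixed ocean phase function
#'
#' @param iop an `ocean_iop` from [assemble_iop_profile()]
#' @param i index into the wavelength grid
#' @param lmax highest Legendre order
#' @return moments chi_0..chi_lmax (chi_0 = 1)
#' @export
ocean_phase_moments <- function(iop, i, lmax) {
  phase_moments_components(iop$w_iso[i], iop$w_ray[i], iop$gamma[i],
                           iop$w_hg[i], iop$g_p, lmax)
}
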