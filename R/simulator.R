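# Two-pass simulation: an elastic excitation pass fixes the in-water light
# field, IPAR and the quenched quantum yield; the emission pass then solves
# the transfer equation at emission wavelengths with the inelastic volume
# sources added.

#' Scene description for a coupled-system simulation
#'
#' Bundles geometry, atmosphere, ocean, quenching and spectral/solver
#' settings. Defaults reproduce the baseline scenario: aerosol optical depth
#' 0.1 at 550 nm, solar zenith 30 degrees, Chla = 1 mg m-3, nadir viewing,
#' excitation grid 370-690 nm at 10 nm, emission grid 640-750 nm at 2.5 nm.
#'
#' @param chla chlorophyll-a concentration [mg m-3] (shorthand; ignored if
#'   `ocean` is supplied)
#' @param tau_a550 aerosol optical depth at 550 nm (shorthand; ignored if
#'   `atmosphere` is supplied)
#' @param theta_s solar zenith angle [deg], 0-89
#' @param theta_v viewing zenith angle [deg] (0 = nadir)
#' @param atmosphere an [atmosphere_state()]
#' @param ocean an [ocean_state()]
#' @param quenching a [quenching_params()]
#' @param emission an [emission_spec()]
#' @param raman a [raman_params()]
#' @param fdom_eta FDOM fluorescence efficiency (0 disables, the default)
#' @param excitation_grid,emission_grid wavelength grids [nm]
#' @param n_mu Gauss nodes per hemisphere
#' @param n_modes azimuth Fourier modes (1 suffices for nadir viewing)
#' @param tol,max_orders solver iteration controls
#' @param n_water_layers number of water layers (surface-refined)
#' @param raman_in_excitation add one Raman iteration to the excitation-pass
#'   scalar irradiance before IPAR is computed (default off: elastic-only
#'   excitation pass)
#' @return object of class `fluorrt_scene`
#' @export
scene <- function(chla = 1, tau_a550 = 0.1, theta_s = 30, theta_v = 0,
                  atmosphere = NULL, ocean = NULL,
                  quenching = quenching_params(),
                  emission = emission_spec(), raman = raman_params(),
                  fdom_eta = 0,
                  excitation_grid = seq(370, 690, by = 10),
                  emission_grid = seq(640, 750, by = 2.5),
                  n_mu = 32, n_modes = 1, tol = 1e-4, max_orders = 100,
                  n_water_layers = 50, raman_in_excitation = FALSE) {
  stopifnot(theta_s >= 0, theta_s <= 89, theta_v >= 0, theta_v < 90)
  if (is.null(atmosphere)) atmosphere <- atmosphere_state(tau_a550 = tau_a550)
  if (is.null(ocean)) ocean <- ocean_state(chla = chla)
  stopifnot(inherits(atmosphere, "atmosphere_state"),
            inherits(ocean, "ocean_state"),
            inherits(quenching, "quenching_params"),
            inherits(emission, "emission_spec"))
  if (any(diff(excitation_grid) <= 0) || any(diff(emission_grid) <= 0)) {
    stop("wavelength grids must be strictly increasing")
  }
  structure(list(
    theta_s = theta_s, theta_v = theta_v, atmosphere = atmosphere,
    ocean = ocean, quenching = quenching, emission = emission,
    raman = raman, fdom_eta = fdom_eta,
    excitation_grid = excitation_grid, emission_grid = emission_grid,
    n_mu = n_mu, n_modes = n_modes, tol = tol, max_orders = max_orders,
    n_water_layers = n_water_layers,
    raman_in_excitation = isTRUE(raman_in_excitation)),
    class = "fluorrt_scene")
}

# Water-column layering: depth spans 3 optical depths at the most
# transparent wavelength of the combined grid (clamped to 30-200 m) so that
# IPAR decays below the quantum-yield saturation scale; layers are
# exponentially refined toward the surface.
water_layer_bounds <- function(sc) {
  wl <- sort(unique(c(sc$excitation_grid, sc$emission_grid)))
  iop <- assemble_iop_profile(sc$ocean, wl)
  a_min <- min(iop$a)
  bottom <- min(max(3 / a_min, 30), 200)
  if (!is.null(sc$ocean$bottom_depth)) bottom <- sc$ocean$bottom_depth
  n <- sc$n_water_layers
  u <- seq(0, 1, length.out = n + 1)
  a <- 4
  bottom * (exp(a * u) - 1) / (exp(a) - 1)
}

# Water part of the layer stack for wavelength index i of an ocean_iop.
build_water_stack <- function(iop, i, z_bounds) {
  dz <- diff(z_bounds)
  nl <- length(dz)
  data.frame(tau = iop$c[i] * dz,
             omega = if (iop$c[i] > 0) iop$b[i] / iop$c[i] else 0,
             medium = "water",
             w_iso = iop$w_iso[i], w_ray = iop$w_ray[i],
             gamma = iop$gamma[i], w_hg = iop$w_hg[i], g = iop$g_p,
             dz = dz, cext = iop$c[i])
}

#' Run the excitation pass
#'
#' Solves the elastic transfer problem at every excitation wavelength,
#' records the scalar irradiance at all water levels, and derives the IPAR
#' and quantum-yield profiles.
#'
#' @param sc a [scene()]
#' @return object of class `excitation_field` with the absolute scalar
#'   irradiance matrix `Eo` [depth level x excitation wavelength,
#'   W m-2 nm-1], depth grid `z` [m], `ipar(z)`, `phi(z)`, and the
#'   excitation-grid IOP components
#' @export
run_excitation_pass <- function(sc) {
  stopifnot(inherits(sc, "fluorrt_scene"))
  wl <- sc$excitation_grid
  iop <- assemble_iop_profile(sc$ocean, wl)
  zb <- water_layer_bounds(sc)
  grid <- angular_grid(sc$n_mu, 1)
  F0 <- solar_irradiance(wl)
  nlev <- length(zb)
  Eo <- matrix(0, nlev, length(wl))
  Ed0 <- numeric(length(wl))
  for (i in seq_along(wl)) {
    air <- build_atmosphere_stack(sc$atmosphere, wl[i])
    st <- layer_stack(air, build_water_stack(iop, i, zb))
    fld <- tryCatch(
      solve_sos(st, sc$theta_s, grid, F0 = 1, max_orders = sc$max_orders,
                tol = sc$tol, out_mu = cos(sc$theta_v * pi / 180)),
      error = function(e) stop("excitation solve failed at ", wl[i],
                               " nm: ", conditionMessage(e)))
    Eo[, i] <- fld$Eo_water * F0[i]
    Ed0[i] <- fld$Ed_water[1] * F0[i]
    if (sc$raman_in_excitation) {
      sr <- raman_source(wl[i], Eo[, seq_len(max(i - 1, 1)), drop = FALSE],
                         wl[seq_len(max(i - 1, 1))], sc$raman)
      if (any(sr > 0)) {
        fr <- solve_sos(st, sc$theta_s, grid, extra_source = sr, F0 = 0,
                        max_orders = sc$max_orders, tol = sc$tol)
        Eo[, i] <- Eo[, i] + fr$Eo_water
      }
    }
  }
  ip <- ipar(Eo, wl, window = sc$emission$window)
  structure(list(Eo = Eo, z = zb, lambda_e = wl, ipar = ip,
                 phi = quantum_yield(ip, sc$quenching),
                 a_p = iop$a_p, a_y = iop$a_y, Ed0 = Ed0, scene = sc),
            class = "excitation_field")
}

#' Run the emission pass
#'
#' Builds the inelastic volume sources from the excitation-pass field and
#' solves the transfer equation at every emission wavelength, producing
#' nadir (or configured) reflectances at the top of the atmosphere and just
#' below the ocean surface.
#'
#' @param sc a [scene()]
#' @param exc an `excitation_field` from [run_excitation_pass()]
#' @param decompose solve each inelastic component separately so that the
#'   spectra carry an elastic/C/R/Y decomposition (slower); otherwise the
#'   components are solved together
#' @return object of class `fluorrt_sim`
#' @export
run_emission_pass <- function(sc, exc, decompose = FALSE) {
  stopifnot(inherits(sc, "fluorrt_scene"),
            inherits(exc, "excitation_field"))
  wl <- sc$emission_grid
  iop <- assemble_iop_profile(sc$ocean, wl)
  zb <- exc$z
  grid <- angular_grid(sc$n_mu, sc$n_modes)
  F0 <- solar_irradiance(wl)
  mu_v <- cos(sc$theta_v * pi / 180)
  n <- length(wl)
  cols <- c("rho_toa", "rho_too", "rho_toa_elastic", "rho_too_elastic",
            "rho_toa_C", "rho_too_C", "rho_toa_R", "rho_too_R",
            "rho_toa_Y", "rho_too_Y")
  out <- matrix(0, n, length(cols), dimnames = list(NULL, cols))
  phi_rel <- sc$theta_v * 0                      # relative azimuth 0
  for (i in seq_len(n)) {
    air <- build_atmosphere_stack(sc$atmosphere, wl[i])
    wdf <- build_water_stack(iop, i, zb)
    st <- layer_stack(air, wdf)
    S_C <- fluorescence_source(wl[i], exc$Eo, exc$lambda_e, exc$a_p,
                               exc$phi, sc$emission)
    S_R <- raman_source(wl[i], exc$Eo, exc$lambda_e, sc$raman)
    S_Y <- fdom_source(wl[i], exc$Eo, exc$lambda_e, exc$a_y,
                       eta = sc$fdom_eta)
    el <- solve_sos(st, sc$theta_s, grid, F0 = 1,
                    max_orders = sc$max_orders, tol = sc$tol,
                    out_mu = mu_v)
    toa_el <- viewing_radiance(el, "toa", phi_rel) * F0[i]
    too_el <- viewing_radiance(el, "too", phi_rel) * F0[i]
    ed_toa <- el$Ed_air[1] * F0[i]               # mu0 * F0
    ed_too <- el$Ed_water[1] * F0[i]
    solve_src <- function(S) {
      if (all(S <= 0)) return(list(toa = 0, too = 0, ed = 0))
      fs <- solve_sos(st, sc$theta_s, grid, extra_source = S, F0 = 0,
                      max_orders = sc$max_orders, tol = sc$tol,
                      out_mu = mu_v)
      list(toa = viewing_radiance(fs, "toa", phi_rel),
           too = viewing_radiance(fs, "too", phi_rel),
           ed = fs$Ed_water[1])
    }
    if (decompose) {
      rc <- solve_src(S_C); rr <- solve_src(S_R); ry <- solve_src(S_Y)
      toa_src <- rc$toa + rr$toa + ry$toa
      too_src <- rc$too + rr$too + ry$too
      ed_src <- rc$ed + rr$ed + ry$ed
    } else {
      rtot <- solve_src(S_C + S_R + S_Y)
      rc <- rr <- ry <- list(toa = NA_real_, too = NA_real_)
      toa_src <- rtot$toa; too_src <- rtot$too; ed_src <- rtot$ed
    }
    ed_too_tot <- ed_too + ed_src
    out[i, ] <- c(pi * (toa_el + toa_src) / ed_toa,
                  pi * (too_el + too_src) / ed_too_tot,
                  pi * toa_el / ed_toa, pi * too_el / ed_too_tot,
                  pi * rc$toa / ed_toa, pi * rc$too / ed_too_tot,
                  pi * rr$toa / ed_toa, pi * rr$too / ed_too_tot,
                  pi * ry$toa / ed_toa, pi * ry$too / ed_too_tot)
  }
  spectra <- data.frame(wavelength = wl, out)
  structure(list(spectra = spectra, ipar = exc$ipar, phi = exc$phi,
                 z = exc$z, Eo = exc$Eo, lambda_e = exc$lambda_e,
                 scene = sc, decomposed = decompose),
            class = "fluorrt_sim")
}

#' Simulate a scene end to end
#'
#' Excitation pass followed by the emission pass.
#'
#' @inheritParams run_emission_pass
#' @return a `fluorrt_sim` (see [run_emission_pass()])
#' @export
simulate_scene <- function(sc, decompose = FALSE) {
  exc <- run_excitation_pass(sc)
  run_emission_pass(sc, exc, decompose = decompose)
}

#' Relative inelastic signal between two simulations
#'
#' \eqn{100\,(\rho_{with} - \rho_{without})/\rho_{without}} per emission
#' wavelength. "Without" is typically the same scene with the fluorescence
#' source disabled, or the Chla = 0 scene for concentration comparisons.
#'
#' @param result_with,result_without `fluorrt_sim` objects on identical
#'   emission grids
#' @param where "too" (default) or "toa"
#' @return data.frame with `wavelength` and `signal` [%]
#' @export
fluorescence_signal <- function(result_with, result_without,
                                where = c("too", "toa")) {
  where <- match.arg(where)
  w1 <- result_with$spectra$wavelength
  w2 <- result_without$spectra$wavelength
  if (length(w1) != length(w2) || any(w1 != w2)) {
    stop("emission grids differ between the two results")
  }
  col <- paste0("rho_", where)
  a <- result_with$spectra[[col]]
  b <- result_without$spectra[[col]]
  data.frame(wavelength = w1, signal = 100 * (a - b) / b)
}

#' Convolve a spectrum with a Gaussian instrument line shape
#'
#' Gaussian kernel of the given full width at half maximum, renormalized
#' where the kernel is truncated by the spectrum edges, so a constant
#' spectrum is preserved exactly.
#'
#' @param wavelength sample wavelengths [nm]
#' @param values spectrum values
#' @param fwhm full width at half maximum [nm]
#' @return convolved values on the same grid
#' @export
convolve_ils <- function(wavelength, values, fwhm = 5) {
  stopifnot(length(wavelength) == length(values), fwhm > 0)
  if (max(diff(wavelength)) > fwhm / 4 + 1e-9) {
    warning("spectrum sampling coarser than fwhm/4; ILS convolution may ",
            "be inaccurate")
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  wts <- trapz_weights(wavelength)
  out <- vapply(seq_along(wavelength), function(i) {
    k <- stats::dnorm(wavelength, wavelength[i], sigma) * wts
    sum(k * values) / sum(k)
  }, numeric(1))
  out
}

#' @export
print.fluorrt_scene <- function(x, ...) {
  cat("fluorrt scene\n")
  cat(sprintf("  solar zenith %g deg, viewing zenith %g deg\n",
              x$theta_s, x$theta_v))
  cat(sprintf("  Chla %.3g mg m-3, CDOM a440 %.4g m-1, tau_a(550) %.3g\n",
              x$ocean$chla, x$ocean$cdom_a440, x$atmosphere$tau_a550))
  cat(sprintf("  quenching: qI %.2f, Ek %g, ET %g, phi %g-%g\n",
              x$quenching$qI, x$quenching$Ek, x$quenching$ET,
              x$quenching$phi_min, x$quenching$phi_max))
  cat(sprintf("  excitation %g-%g nm (%d), emission %g-%g nm (%d)\n",
              min(x$excitation_grid), max(x$excitation_grid),
              length(x$excitation_grid), min(x$emission_grid),
              max(x$emission_grid), length(x$emission_grid)))
  invisible(x)
}

#' @export
print.fluorrt_sim <- function(x, ...) {
  cat("fluorrt simulation result\n")
  print(x$scene)
  i680 <- which.min(abs(x$spectra$wavelength - 680))
  cat(sprintf("  rho_TOO(%g nm) = %.4g, rho_TOA(%g nm) = %.4g\n",
              x$spectra$wavelength[i680], x$spectra$rho_too[i680],
              x$spectra$wavelength[i680], x$spectra$rho_toa[i680]))
  cat(sprintf("  surface IPAR %.4g umol quanta m-2 s-1, PhiC %.4g\n",
              x$ipar[1], x$phi[1]))
  invisible(x)
}

#' @export
summary.fluorrt_sim <- function(object, ...) {
  sp <- object$spectra
  pk <- sp$wavelength[which.max(sp$rho_too)]
  structure(list(
    rho_too_680 = sp$rho_too[which.min(abs(sp$wavelength - 680))],
    rho_toa_680 = sp$rho_toa[which.min(abs(sp$wavelength - 680))],
    too_peak_wavelength = pk,
    ipar_surface = object$ipar[1],
    phi_surface = object$phi[1],
    phi_max = max(object$phi),
    phi_peak_depth = object$z[which.max(object$phi)]),
    class = "summary.fluorrt_sim")
}

#' @export
print.summary.fluorrt_sim <- function(x, ...) {
  cat("fluorrt simulation summary\n")
  cat(sprintf("  rho_TOO(680) %.4g   rho_TOA(680) %.4g\n",
              x$rho_too_680, x$rho_toa_680))
  cat(sprintf("  TOO spectral peak at %g nm\n", x$too_peak_wavelength))
  cat(sprintf("  IPAR(0-) %.4g umol quanta m-2 s-1\n", x$ipar_surface))
  cat(sprintf("  PhiC: surface %.4g, max %.4g at %.3g m\n",
              x$phi_surface, x$phi_max, x$phi_peak_depth))
  invisible(x)
}

#' @export
plot.fluorrt_sim <- function(x, which = c("spectra", "profiles"), ...) {
  which <- match.arg(which)
  if (which == "spectra") {
    sp <- x$spectra
    graphics::matplot(sp$wavelength, cbind(sp$rho_too, sp$rho_toa),
                      type = "l", lty = 1, col = c("seagreen", "steelblue"),
                      xlab = "wavelength [nm]", ylab = "reflectance", ...)
    graphics::legend("topright", c("TOO", "TOA"), lty = 1,
                     col = c("seagreen", "steelblue"), bty = "n")
  } else {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
    graphics::plot(x$ipar, -x$z, type = "l", xlab = "IPAR", ylab = "-z [m]")
    graphics::plot(x$phi, -x$z, type = "l", xlab = "quantum yield",
                   ylab = "-z [m]")
  }
  invisible(x)
}
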