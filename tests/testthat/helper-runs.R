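# Shared cache of full-default scenario runs used by the acceptance tests:
# each scenario is simulated once per test session.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

acc_sim <- function(chla, tau_a550 = 0.1, theta_s = 30) {
  key <- sprintf("sim_%g_%g_%g", chla, tau_a550, theta_s)
  cached(key, suppressWarnings(
    simulate_scene(scene(chla = chla, tau_a550 = tau_a550,
                         theta_s = theta_s))))
}

acc_exc <- function(chla, tau_a550 = 0.1, theta_s = 30) {
  key <- sprintf("exc_%g_%g_%g", chla, tau_a550, theta_s)
  cached(key, suppressWarnings(
    run_excitation_pass(scene(chla = chla, tau_a550 = tau_a550,
                              theta_s = theta_s))))
}

acc_sim_dec <- function(chla, tau_a550 = 0.1, theta_s = 30, gas = TRUE) {
  key <- sprintf("simdec_%g_%g_%g_%d", chla, tau_a550, theta_s, gas)
  cached(key, suppressWarnings(
    simulate_scene(scene(chla = chla,
                         atmosphere = atmosphere_state(
                           tau_a550 = tau_a550, gas_absorption = gas),
                         theta_s = theta_s),
                   decompose = TRUE)))
}

convolve_ils_quiet <- function(wavelength, values, fwhm = 5) {
  suppressWarnings(convolve_ils(wavelength, values, fwhm))
}

peak_signal <- function(sim_a, sim_b, lo = 660, hi = 720) {
  s <- fluorescence_signal(sim_a, sim_b, "too")
  k <- s$wavelength >= lo & s$wavelength <= hi
  max(s$signal[k])
}
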