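test_that("scene validates its inputs", {
  expect_error(scene(theta_s = 95))
  expect_error(scene(theta_s = -1))
  expect_error(scene(excitation_grid = c(400, 390)), "increasing")
  sc <- scene()
  expect_s3_class(sc, "fluorrt_scene")
  expect_equal(sc$atmosphere$tau_a550, 0.1)
  expect_equal(sc$theta_s, 30)
  expect_output(print(sc), "solar zenith 30")
})

test_that("excitation pass produces attenuating, chla-consistent fields", {
  e1 <- run_excitation_pass(mini_scene(chla = 0.1))
  e2 <- run_excitation_pass(mini_scene(chla = 10))
  expect_true(all(e1$Eo >= 0))
  # IPAR decreasing with depth (to within the solver tolerance locally)
  expect_true(all(diff(e1$ipar) < 1e-3 * head(e1$ipar, -1)))
  expect_true(all(diff(e2$ipar) < 1e-3 * head(e2$ipar, -1)))
  # IPAR decreases faster in greener water
  expect_gt(e1$ipar[10] / e1$ipar[1], e2$ipar[10] / e2$ipar[1])
  # surface quantum yield nearly independent of chla
  expect_equal(e1$phi[1], e2$phi[1], tolerance = 5e-3)
  # quantum yield has an interior maximum that is shallower at high chla
  expect_gt(which.max(e2$phi), 1)
  expect_lt(e2$z[which.max(e2$phi)], e1$z[which.max(e1$phi)])
})

test_that("transfer is linear in the inelastic volume source", {
  sc <- mini_scene(chla = 1)
  iop <- fluorrt:::assemble_iop_profile(sc$ocean, 685)
  zb <- fluorrt:::water_layer_bounds(sc)
  air <- build_atmosphere_stack(sc$atmosphere, 685)
  st <- layer_stack(air, fluorrt:::build_water_stack(iop, 1, zb))
  S <- 1e-5 * exp(-zb / 5)
  g <- angular_grid(8, 1)
  f1 <- solve_sos(st, 30, g, extra_source = S, F0 = 0, tol = 1e-7)
  f2 <- solve_sos(st, 30, g, extra_source = 2 * S, F0 = 0, tol = 1e-7)
  # doubling the source (e.g. the quantum yield) doubles the emitted field
  expect_equal(2 * viewing_radiance(f1, "too"),
               viewing_radiance(f2, "too"), tolerance = 1e-9)
  # elastic + source-only equals the combined solve (superposition)
  fe <- solve_sos(st, 30, g, F0 = 1, tol = 1e-8)
  fc <- solve_sos(st, 30, g, extra_source = S, F0 = 1, tol = 1e-8)
  expect_equal(viewing_radiance(fe, "toa") + viewing_radiance(f1, "toa"),
               viewing_radiance(fc, "toa"), tolerance = 1e-4)
})

test_that("no fluorophore means no emission line", {
  sc <- mini_scene(chla = 0, raman = raman_params(enabled = FALSE),
                   atmosphere = atmosphere_state(gas_absorption = FALSE))
  r <- suppressWarnings(simulate_scene(sc, decompose = TRUE))
  expect_equal(r$spectra$rho_too_C, rep(0, nrow(r$spectra)))
  # pure-water spectrum falls monotonically across the red: no 685 nm bump
  expect_true(all(diff(r$spectra$rho_too) < 0))
})

test_that("fluorescence emission peaks at the line center below water", {
  r <- acc_sim_dec(10, gas = FALSE)
  sp <- r$spectra
  pk <- sp$wavelength[which.max(sp$rho_too_C)]
  expect_lte(abs(pk - 685), 2)
  # spectral support: the fluorescence contribution exceeds 1% of its peak
  # over roughly 660-720 nm and nowhere far outside it
  # (water reabsorption truncates the red wing a little below the bare
  # Gaussian's 1% point)
  above <- sp$wavelength[sp$rho_too_C > 0.01 * max(sp$rho_too_C)]
  expect_lte(min(above), 665)
  expect_gte(min(above), 645)
  expect_gte(max(above), 705)
  expect_lte(max(above), 725)
})

test_that("oxygen-band absorption shifts the apparent TOA peak blueward", {
  r <- acc_sim_dec(10, gas = TRUE)
  sp <- r$spectra
  toa_c <- convolve_ils_quiet(sp$wavelength, sp$rho_toa_C)
  pk_toa <- sp$wavelength[which.max(toa_c)]
  expect_lt(pk_toa, 685)
  expect_gte(pk_toa, 677.5)
})

test_that("chla strengthens the below-surface reflectance everywhere", {
  r10 <- acc_sim(10); r0 <- acc_sim(0)
  d <- r10$spectra$rho_too - r0$spectra$rho_too
  expect_true(all(d > 0))
})

test_that("relative-signal arithmetic is exact", {
  r <- acc_sim(10)
  s0 <- fluorescence_signal(r, r, "too")
  expect_equal(s0$signal, rep(0, nrow(s0)))
  r2 <- r
  r2$spectra$rho_too <- 1.02 * r$spectra$rho_too
  expect_equal(fluorescence_signal(r2, r, "too")$signal,
               rep(2, nrow(s0)), tolerance = 1e-12)
  r3 <- r
  r3$spectra$wavelength <- r$spectra$wavelength + 1
  expect_error(fluorescence_signal(r3, r), "grids differ")
})

test_that("ILS convolution preserves constants and spike areas", {
  wl <- seq(640, 750, 1)
  expect_equal(convolve_ils(wl, rep(3, length(wl))), rep(3, length(wl)))
  spike <- as.numeric(wl == 695)
  out <- convolve_ils(wl, spike)
  # area preserved
  expect_equal(sum(out), sum(spike), tolerance = 1e-6)
  # width: half maximum crossings ~5 nm apart
  half <- range(wl[out >= max(out) / 2])
  expect_equal(diff(half) + 1, 5, tolerance = 0.5)
  # Gaussian shape against closed form
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  expect_equal(out, dnorm(wl, 695, sigma) / sum(dnorm(wl, 695, sigma)),
               tolerance = 1e-6)
  expect_warning(convolve_ils(seq(640, 750, 2.5), rep(1, 45)), "coarser")
})

test_that("simulation results print and summarize", {
  r <- acc_sim(10)
  expect_output(print(r), "rho_TOO")
  s <- summary(r)
  expect_output(print(s), "IPAR")
  expect_gt(s$ipar_surface, 0)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(r))
  expect_silent(plot(r, "profiles"))
})
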