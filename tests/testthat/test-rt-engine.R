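test_that("Fresnel coefficients match closed forms", {
  # normal incidence on water
  f <- fresnel(1, 1.34)
  expect_equal(f$R, (0.34 / 2.34)^2, tolerance = 1e-12)
  expect_equal(f$mu_t, 1)
  # index ratio 1: no reflection, no bending
  f1 <- fresnel(0.63, 1)
  expect_equal(f1$R, 0)
  expect_equal(f1$mu_t, 0.63)
  # total internal reflection beyond the critical angle (sin qc = 1/n)
  mu_c <- sqrt(1 - 1 / 1.34^2)
  expect_equal(fresnel(mu_c - 1e-3, 1 / 1.34)$R, 1)
  expect_lt(fresnel(mu_c + 1e-2, 1 / 1.34)$R, 1)
  # energy: R + T = 1
  f2 <- fresnel(seq(0.05, 1, 0.05), 1.34)
  expect_equal(f2$R + f2$Tf, rep(1, 20))
})

test_that("interface matrices conserve flux", {
  g <- gauss_hemisphere(16)
  ifc <- fluorrt:::interface_matrices(g$mu, g$w, 1.34)
  L <- 1 + g$mu^2                       # arbitrary incident distribution
  inc <- sum(g$w * g$mu * L)
  # air-incident: reflected + transmitted = incident
  trans <- sum(g$w * g$mu * (ifc$T_aw %*% L))
  refl <- sum(g$w * g$mu * (ifc$R_a * L))
  expect_equal(trans + refl, inc, tolerance = 1e-12)
  # water-incident
  trans_w <- sum(g$w * g$mu * (ifc$T_wa %*% L))
  refl_w <- sum(g$w * g$mu * (ifc$R_w * L))
  expect_equal(trans_w + refl_w, inc, tolerance = 1e-12)
})

test_that("single scattering reproduces the closed-form slab reflectance", {
  # omega = 1, isotropic, tau = 0.01, mu = mu0 = 1:
  # rho_1 = (omega/(4(mu+mu0))) (1 - exp(-tau(1/mu+1/mu0))) = 0.0024751
  rho_cf <- (1 / 8) * (1 - exp(-0.02))
  # isolate the first order by linearity in omega (order n scales omega^n)
  eps <- 1e-6
  st <- slab_stack(0.01, eps, nsub = 4)
  f <- solve_sos(st, 0, angular_grid(16, 1))
  rho1 <- pi * viewing_radiance(f, "toa") / f$Ed_air[1] / eps
  expect_equal(rho1, rho_cf, tolerance = 1e-3)
  # the full conservative solution adds the higher orders; checked against
  # an independently computed second-order integral (6.845e-5)
  st1 <- slab_stack(0.01, 1, nsub = 4)
  f1 <- solve_sos(st1, 0, angular_grid(16, 1), tol = 1e-7)
  rho <- pi * viewing_radiance(f1, "toa") / f1$Ed_air[1]
  expect_equal(rho, rho_cf + 6.845e-5, tolerance = 0.005)
})

test_that("zero optical depth over a black ocean gives zero radiance", {
  air <- data.frame(tau = 0, omega = 0, medium = "air", w_iso = 1,
                    w_ray = 0, gamma = 0, w_hg = 0, g = 0,
                    dz = NA_real_, cext = NA_real_)
  st <- layer_stack(air)
  f <- solve_sos(st, 30, angular_grid(8, 1), out_mu = c(0.5, 1))
  expect_equal(viewing_radiance(f, "toa"), c(0, 0))
})

test_that("a conservative column conserves flux to 0.5%", {
  st <- slab_stack(1, 1, nsub = 20, w_iso = 0, w_ray = 1, gamma = 0.0144)
  mu0 <- 0.6
  f <- solve_sos(st, acos(mu0) * 180 / pi, angular_grid(16, 1),
                 max_orders = 400, tol = 1e-8)
  refl <- f$Eu_air[1]
  trans <- f$Ed_air[length(f$Ed_air)]
  expect_equal((refl + trans) / mu0, 1, tolerance = 0.005)
})

test_that("scattering orders decay geometrically for omega < 1", {
  st <- slab_stack(2, 0.8, nsub = 20)
  f <- solve_sos(st, 30, angular_grid(8, 1), tol = 1e-9, max_orders = 200)
  contrib <- f$order_contrib
  late <- contrib[-(1:3)]
  expect_true(all(diff(log(late[late > 0])) < 0))
})

test_that("TOA reflectance is reciprocal in solar/viewing direction", {
  st <- slab_stack(0.5, 0.9, nsub = 10, w_iso = 0, w_hg = 1, g = 0.5)
  mu_a <- 0.9; mu_b <- 0.55
  f_ab <- solve_sos(st, acos(mu_a) * 180 / pi, angular_grid(16, 1),
                    tol = 1e-8, out_mu = mu_b)
  f_ba <- solve_sos(st, acos(mu_b) * 180 / pi, angular_grid(16, 1),
                    tol = 1e-8, out_mu = mu_a)
  # R(mu0, muv) = pi I / (mu0 F0) is symmetric (azimuth-averaged)
  r_ab <- pi * viewing_radiance(f_ab, "toa") / f_ab$Ed_air[1]
  r_ba <- pi * viewing_radiance(f_ba, "toa") / f_ba$Ed_air[1]
  expect_equal(r_ab, r_ba, tolerance = 2e-3)
})

test_that("radiances agree with a Monte-Carlo photon oracle within 3 sigma", {
  # two-layer slab: Rayleigh-free test with isotropic + HG layers
  tau <- c(0.3, 0.4); omega <- c(0.9, 0.7); g <- c(0, 0.6); mu0 <- 0.8
  mc <- mc_slab(tau, omega, g, mu0, n_photons = 2e6, seed = 42)
  st <- slab_stack(tau, omega, nsub = 30,
                   w_iso = c(1, 0), w_hg = c(0, 1), g = g)
  f <- solve_sos(st, acos(mu0) * 180 / pi, angular_grid(16, 1), tol = 1e-7,
                 max_orders = 300)
  gq <- f$grid
  # hemispheric fluxes (fractions of incident)
  R_sos <- f$Eu_air[1] / (mu0 * f$F0)
  T_sos <- (f$Ed_air[length(f$Ed_air)] -
              f$beams$air_dn[length(f$beams$air_dn)] * mu0) / (mu0 * f$F0)
  expect_lt(abs(R_sos - mc$mean["R"]), 3 * mc$se["R"])
  expect_lt(abs(T_sos - (mc$mean["T"] - exp(-sum(tau) / mu0))),
            3 * mc$se["T"])
  # flux-weighted bin radiances of the reflected field
  Iup <- f$air$I_up[, 1]
  for (k in 1:2) {
    lo <- c(0, 0.5)[k]; hi <- c(0.5, 1)[k]
    inb <- gq$mu > lo & gq$mu <= hi
    L_sos <- 2 * pi * sum(gq$w[inb] * gq$mu[inb] * Iup[inb]) /
      (pi * (hi^2 - lo^2))
    key <- paste0("bin", k)
    expect_lt(abs(L_sos - mc$mean[key]), 3 * mc$se[key])
  }
})

test_that("irradiance accessors recover simple fields", {
  # near-transparent atmosphere: direct beam only, Eo = F0, Ed = mu0 F0
  st <- slab_stack(1e-8, 0, nsub = 2)
  mu0 <- 0.7
  f <- solve_sos(st, acos(mu0) * 180 / pi, angular_grid(8, 1))
  nl <- length(f$Eo_air)
  expect_equal(scalar_irradiance(f, nl, "air"), 1, tolerance = 1e-6)
  expect_equal(downwelling_irradiance(f, nl, "air"), mu0, tolerance = 1e-6)
  expect_error(scalar_irradiance(f, nl + 1, "air"), "level")
})

test_that("quadrature scalar irradiance matches a dense-grid oracle", {
  # smooth anisotropic field L(mu) = 1 + 0.8 mu + 0.3 mu^2, both hemispheres
  g <- gauss_hemisphere(16)
  Ldn <- 1 + 0.8 * g$mu + 0.3 * g$mu^2
  Lup <- 1 - 0.5 * g$mu
  Eo_q <- 2 * pi * sum(g$w * (Ldn + Lup))
  mu_d <- seq(0, 1, length.out = 20001)
  wts <- fluorrt:::trapz_weights(mu_d)
  Eo_d <- 2 * pi * (sum(wts * (1 + 0.8 * mu_d + 0.3 * mu_d^2)) +
                      sum(wts * (1 - 0.5 * mu_d)))
  expect_equal(Eo_q / Eo_d, 1, tolerance = 1e-4)
})

test_that("reflectance follows its definition and guards Ed = 0", {
  expect_equal(reflectance(1 / pi, 1), 1)
  expect_equal(reflectance(0, 2), 0)
  expect_equal(reflectance(0.01, 1), 0.031416, tolerance = 1e-4)
  expect_error(reflectance(1, 0), "Ed")
})

test_that("doubling the angular resolution barely changes nadir radiance", {
  # baseline scene at one emission wavelength, at the simulator's default
  # 32 streams per hemisphere
  sc <- scene(chla = 1)
  iop <- fluorrt:::assemble_iop_profile(sc$ocean, 680)
  zb <- fluorrt:::water_layer_bounds(sc)
  air <- build_atmosphere_stack(sc$atmosphere, 680)
  st <- layer_stack(air, fluorrt:::build_water_stack(iop, 1, zb))
  f32 <- solve_sos(st, 30, angular_grid(32, 1), tol = 1e-6)
  f64 <- solve_sos(st, 30, angular_grid(64, 1), tol = 1e-6)
  r32 <- pi * viewing_radiance(f32, "toa") / f32$Ed_air[1]
  r64 <- pi * viewing_radiance(f64, "toa") / f64$Ed_air[1]
  expect_equal(r32 / r64, 1, tolerance = 0.002)
})

test_that("invalid layer inputs are rejected", {
  air <- data.frame(tau = -1, omega = 0.5, medium = "air", w_iso = 1,
                    w_ray = 0, gamma = 0, w_hg = 0, g = 0,
                    dz = NA_real_, cext = NA_real_)
  expect_error(layer_stack(air), "tau")
  air$tau <- 1; air$omega <- 1.5
  expect_error(layer_stack(air), "omega")
})
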