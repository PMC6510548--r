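test_that("IPAR reproduces the flat-spectrum closed form", {
  wl <- seq(370, 690, 10)
  # integrand linear in lambda, so the trapezoid rule is exact:
  # (1/hc) * mean(lambda) * width, in micromole quanta
  hc <- 6.62607015e-34 * 2.99792458e8
  exact <- 530e-9 * 320 / hc / 6.02214076e23 * 1e6
  expect_equal(ipar(rep(1, length(wl)), wl), exact, tolerance = 1e-10)
  expect_equal(ipar(rep(0, length(wl)), wl), 0)
  # linearity
  expect_equal(ipar(rep(0.5, length(wl)), wl), exact / 2, tolerance = 1e-10)
  # matrix input: one value per depth row
  m <- rbind(rep(1, length(wl)), rep(2, length(wl)))
  expect_equal(ipar(m, wl), c(exact, 2 * exact), tolerance = 1e-10)
  expect_error(ipar(1, 500, window = c(370, 380)), "window")
})

test_that("quantum yield evaluates the quenching model exactly", {
  qp <- quenching_params()
  expect_equal(quantum_yield(0, qp), 0.35 * 0.03, tolerance = 1e-12)
  expect_equal(quantum_yield(1500, qp),
               0.35 * exp(-1500 / 634) *
                 (0.03 * exp(-1500 / 55) + 0.09 * (1 - exp(-1500 / 55))),
               tolerance = 1e-12)
  expect_equal(round(quantum_yield(1500, qp), 6), 0.002957)
  expect_equal(quantum_yield(55, qp),
               0.35 * exp(-55 / 634) *
                 (0.03 * exp(-1) + 0.09 * (1 - exp(-1))),
               tolerance = 1e-12)
  expect_equal(round(quantum_yield(55, qp), 6), 0.021799)
})

test_that("quantum yield is bounded, continuous, and vanishes at high light", {
  qp <- quenching_params()
  ip <- seq(0, 20000, by = 0.5)
  phi <- quantum_yield(ip, qp)
  expect_true(all(phi >= 0 & phi <= qp$qI * qp$phi_max))
  expect_lt(phi[length(phi)], 1e-10)
  expect_true(all(abs(diff(phi)) < 5e-4))   # no jumps on a fine grid
  # interior maximum matches a dense numeric scan refined by optimize
  scan <- ip[which.max(phi)]
  opt <- stats::optimize(function(x) quantum_yield(x, qp),
                         c(scan - 1, scan + 1), maximum = TRUE)
  expect_equal(max(phi), opt$objective, tolerance = 1e-6)
})

test_that("fluorescence scattering coefficient matches its closed form", {
  sp <- emission_spec()
  expect_equal(fluorescence_b(685, 550, 0.01, 0.01, sp),
               1e-4 / (sqrt(2 * pi) * 10.6) * (550 / 685),
               tolerance = 1e-12)
  expect_equal(fluorescence_b(685, 550, 0.01, 0.01, sp) * 1e6,
               3.0217, tolerance = 1e-3)
  expect_equal(fluorescence_b(685, 550, 0.01, 0, sp), 0)
  # excitation outside 370-690 nm contributes nothing
  expect_equal(fluorescence_b(685, 700, 0.01, 0.01, sp), 0)
  expect_equal(fluorescence_b(685, 360, 0.01, 0.01, sp), 0)
})

test_that("fluorescence source integrates the excitation field", {
  sp <- emission_spec()
  # single-bin quadrature: Eo concentrated at one excitation wavelength
  wl_e <- c(540, 550, 560)
  Eo <- matrix(c(0, 2, 0), 1)
  s <- fluorescence_source(685, Eo, wl_e, a_p = rep(0.01, 3), phi = 0.01,
                           spec = sp)
  expect_equal(s, fluorescence_b(685, 550, 0.01, 0.01, sp) * 2 * 10 /
                 (4 * pi), tolerance = 1e-12)
  # zero excitation
  expect_equal(fluorescence_source(685, matrix(0, 1, 3), wl_e,
                                   rep(0.01, 3), 0.01, sp), 0)
  # flat Eo, constant a_p phi: matches a dense-grid oracle of
  # int Gaussian * (lambda_e/lambda) dlambda_e / (4 pi)
  wl_e <- seq(370, 690, 10)
  s <- fluorescence_source(685, matrix(1, 1, length(wl_e)), wl_e,
                           rep(1, length(wl_e)), 1, sp)
  fine <- seq(370, 690, 0.05)
  oracle <- sum(fluorrt:::trapz_weights(fine) *
                  exp(-(685 - 685)^2) / (sqrt(2 * pi) * 10.6) *
                  fine / 685) / (4 * pi)
  expect_equal(s, oracle, tolerance = 1e-3)
  # linear in Eo and phi
  s2 <- fluorescence_source(685, matrix(2, 1, length(wl_e)), wl_e,
                            rep(1, length(wl_e)), 1, sp)
  s3 <- fluorescence_source(685, matrix(1, 1, length(wl_e)), wl_e,
                            rep(1, length(wl_e)), 2, sp)
  expect_equal(s2, 2 * s)
  expect_equal(s3, 2 * s)
  expect_error(fluorescence_source(685, matrix(1, 1, 3), wl_e,
                                   rep(1, length(wl_e)), 1, sp),
               "grid mismatch")
})

test_that("Raman redistribution is normalized and peaks at the shift", {
  rp <- raman_params()
  lam <- seq(560, 800, 0.02)
  f <- fluorrt:::raman_redistribution(lam, 550, rp)
  expect_equal(sum(f * 0.02), 1, tolerance = 1e-4)
  # peak near 1/(1/550 - 3350e-7) ~ 662 nm
  expect_equal(lam[which.max(f)], 1 / (1 / 550 - 3350e-7), tolerance = 1)
  # disabled -> zero source
  off <- raman_params(enabled = FALSE)
  wl_e <- seq(500, 600, 10)
  expect_equal(raman_source(662, matrix(1, 1, 11), wl_e, off), 0)
  on <- raman_source(662, matrix(1, 1, 11), wl_e, rp)
  expect_gt(on, 0)
})

test_that("FDOM source is off by default and bounded by absorbed power", {
  wl_e <- seq(370, 690, 10)
  Eo <- matrix(1, 1, length(wl_e))
  a_y <- cdom_absorption(wl_e, 0.1)
  expect_equal(fdom_source(500, Eo, wl_e, a_y), 0)
  expect_equal(fdom_source(500, Eo, wl_e, a_y, eta = 0), 0)
  # emitted power <= eta x absorbed power per unit volume
  eta <- 0.01
  lam_out <- seq(300, 900, 0.5)
  emitted <- sum(vapply(lam_out, function(l)
    fdom_source(l, Eo, wl_e, a_y, eta = eta), numeric(1)) * 0.5) * 4 * pi
  absorbed <- sum(fluorrt:::trapz_weights(wl_e) * a_y * 1)
  expect_lte(emitted, eta * absorbed * (1 + 1e-6))
  expect_gt(emitted, 0)
})

test_that("parameter containers validate their invariants", {
  expect_error(quenching_params(qI = 1.5))
  expect_error(quenching_params(Ek = -1))
  expect_error(quenching_params(phi_min = 0.1, phi_max = 0.05))
  expect_error(emission_spec(sigma = 0))
  expect_error(emission_spec(window = c(700, 600)))
})
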