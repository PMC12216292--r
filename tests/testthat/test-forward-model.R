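# forward model: permittivity, transfer-matrix beta, finite dipole,
# demodulation, referencing, object profiles

test_that("Lorentz permittivity: identity, on-resonance value, linearity", {
  grid <- seq(1400, 1800, by = 4)
  flat <- lorentz_permittivity(NULL, 2.1, grid)
  expect_equal(flat$epsilon, rep(2.1 + 0i, length(grid)))

  # at nu = nu_j the oscillator contributes Im eps = S nu_j / gamma
  osc <- data.frame(center_cm1 = 1600, strength = 0.08, damping_cm1 = 25)
  ps <- lorentz_permittivity(osc, 2.1, c(1500, 1600, 1700))
  expect_equal(Im(ps$epsilon[2]), 0.08 * 1600 / 25, tolerance = 1e-12)

  o2 <- data.frame(center_cm1 = c(1500, 1700), strength = c(0.05, 0.02),
                   damping_cm1 = c(20, 30))
  both <- lorentz_permittivity(o2, 2.1, grid)
  a <- lorentz_permittivity(o2[1, ], 2.1, grid)
  b <- lorentz_permittivity(o2[2, ], 0, grid)
  expect_equal(both$epsilon, a$epsilon + b$epsilon, tolerance = 1e-13)

  expect_error(lorentz_permittivity(
    data.frame(center_cm1 = 1600, strength = 0.1, damping_cm1 = 0), 2, grid),
    "damping")
})

test_that("beta_layers: interface closed forms and multilayer recursion", {
  s2l <- layer_stack(layer(1), layer(4))
  q <- c(0.001, 0.05, 1, 7)
  expect_equal(beta_layers(s2l, q), rep(0.6 + 0i, 4), tolerance = 1e-12)

  # film identical to substrate is invisible
  s3l <- layer_stack(layer(1), layer(4, 10), layer(4))
  expect_equal(beta_layers(s3l, q), rep(0.6 + 0i, 4), tolerance = 1e-12)

  # independent closed-form 3-interface algebra (oracle, coded here)
  e1 <- 1; e2 <- 4 + 0i; e3 <- 1 + 0i; d <- 10; qq <- 1
  r12 <- (e2 - e1) / (e2 + e1); r23 <- (e3 - e2) / (e3 + e2)
  oracle <- (r12 + r23 * exp(-2 * qq * d)) / (1 + r12 * r23 * exp(-2 * qq * d))
  got <- beta_layers(layer_stack(layer(1), layer(4, 10), layer(1)), qq)
  expect_equal(got, oracle, tolerance = 1e-12)

  expect_error(beta_layers(layer_stack(layer(1), layer(-1 + 0i)), 1),
               "singular")
  expect_error(beta_layers(s2l, c(1, 0)), "q must be > 0")
})

test_that("inserting a zero-thickness layer leaves beta(q) unchanged", {
  q <- exp(seq(log(1e-4), log(5), length.out = 40))
  base <- sin_d2o_stack()
  for (eps0 in c(2, 7 + 0.5i)) {
    padded <- layer_stack(layer(1), layer(4, 10), layer(eps0, 0),
                          layer(1.69 + 0.35i))
    expect_lt(max(Mod(beta_layers(padded, q, 1600) -
                      beta_layers(base, q, 1600))), 1e-12)
  }
})

test_that("beta_effective: contrast-free, 2-layer exactness, quadrature oracle", {
  expect_equal(beta_effective(uniform_stack(2 + 0i), c(5, 50)),
               rep(0 + 0i, 2), tolerance = 1e-12)

  b <- beta_effective(layer_stack(layer(1), layer(11.7)), 30)
  expect_equal(b, (11.7 - 1) / (11.7 + 1) + 0i, tolerance = 1e-12)

  # high-resolution trapezoid oracle on an independent q grid
  stk <- sin_d2o_stack()
  z <- c(10, 50, 200)
  oracle <- vapply(z, function(zz) {
    q <- exp(seq(log(1e-6), log(50), length.out = 1e5))
    e1 <- 1; e2 <- 4 + 0i; e3 <- 1.69 + 0.35i
    r12 <- (e2 - e1) / (e2 + e1); r23 <- (e3 - e2) / (e3 + e2)
    bq <- (r12 + r23 * exp(-2 * q * 10)) / (1 + r12 * r23 * exp(-2 * q * 10))
    w <- c(diff(q), 0) / 2 + c(0, diff(q)) / 2
    sum(bq * q * exp(-2 * q * zz) * w) / sum(q * exp(-2 * q * zz) * w)
  }, complex(1))
  got <- beta_effective(stk, z)
  expect_lt(max(Mod(got - oracle) / Mod(oracle)), 1e-4)

  expect_error(beta_effective(stk, 0), "z must be > 0")
})

test_that("fdm_contrast: no-sample limit, decay, double-implementation oracle", {
  tip <- default_tip()
  expect_equal(fdm_contrast(tip, uniform_stack(), c(0, 40, 120)),
               rep(1 + 0i, 3), tolerance = 1e-12)

  si <- si_stack()
  expect_lt(Mod(fdm_contrast(tip, si, 200) - 1),
            Mod(fdm_contrast(tip, si, 0) - 1))

  # independent transcription of the closed form (oracle)
  r <- 60; L <- 300; g <- 0.7 * exp(1i * 0.06); H <- 0
  beta <- (11.7 - 1) / (11.7 + 1)
  W0 <- 1.31 * r * L / (L + 2 * r); W1 <- r / 2
  f0 <- (g - (r + 2 * H + W0) / (2 * L)) * log(4 * L / (r + 4 * H + 2 * W0)) /
    log(4 * L / r)
  f1 <- (g - (r + 2 * H + W1) / (2 * L)) * log(4 * L / (r + 4 * H + 2 * W1)) /
    log(4 * L / r)
  oracle <- 1 + beta * f0 / (2 * (1 - beta * f1))
  expect_equal(fdm_contrast(tip, si, 0), oracle, tolerance = 1e-12)

  expect_error(fdm_contrast(tip, si, -1), "H must be >= 0")
})

test_that("demodulate: harmonics of constant signal vanish; FFT matches quadrature", {
  tip <- default_tip()
  for (n in 1:4)
    expect_lt(demodulate(tip, uniform_stack(), harmonic_n = n)$s_n, 1e-14)

  si <- si_stack()
  d2 <- demodulate(tip, si, harmonic_n = 2)
  d3 <- demodulate(tip, si, harmonic_n = 3)
  expect_lt(d3$s_n, d2$s_n)
  expect_equal(d2$s_n, Mod(d2$sigma_n))
  expect_gt(d2$phi_n, -180); expect_lte(d2$phi_n, 180)

  # brute-force trapezoid quadrature of the same integral (1e4 points)
  th <- seq(0, 2 * pi, length.out = 10001)[-10001]
  sig <- fdm_contrast(tip, si, tip$min_height + tip$a * (1 + cos(th)))
  oracle <- sum(sig * exp(-2i * th)) * (th[2] - th[1]) / (2 * pi)
  expect_lt(Mod(d2$sigma_n - oracle) / Mod(oracle), 1e-8)

  expect_error(demodulate(tip, si, n_theta_samples = 100), "power of two")
  expect_error(demodulate(tip, si, harmonic_n = 40, n_theta_samples = 64),
               "too small")
  expect_error(demodulate(tip, si, harmonic_n = 0), "integer >= 1")
})

test_that("normalized_spectrum: self-reference, lossless phase, cis/trans direction", {
  tip <- default_tip()
  si <- si_stack()
  grid <- c(1500, 1603)
  self <- normalized_spectrum(tip, si, si, grid)
  expect_equal(self$s_ratio, c(1, 1), tolerance = 1e-12)
  expect_equal(self$phi_diff_deg, c(0, 0), tolerance = 1e-9)

  # lossless media + real tip factor: zero referenced phase
  tipr <- real_g_tip()
  s_re <- layer_stack(layer(1), layer(4, 10), layer(2.25))
  ns <- normalized_spectrum(tipr, s_re, si, grid)
  expect_lt(max(abs(ns$phi_diff_deg)), 1e-9)

  # weakening the 1603 cm-1 band (cis surrogate) lowers the referenced phase
  mats <- builtin_materials()
  stk <- function(m) layer_stack(layer(1), layer(mats$sin, 10), layer(m))
  tr <- normalized_spectrum(tip, stk(mats$lipid_trans), stk(mats$si), 1603)
  ci <- normalized_spectrum(tip, stk(mats$lipid_cis), stk(mats$si), 1603)
  expect_lt(ci$phi_diff_deg, tr$phi_diff_deg)
})

test_that("referenced phase at a band center grows monotonically with strength", {
  tip <- default_tip()
  si <- si_stack()
  # weak-band regime (peak Im eps up to ~0.5); the response saturates and
  # turns over for much stronger bands
  phis <- vapply(seq(5e-4, 8e-3, length.out = 8), function(S) {
    m <- lorentz_permittivity(
      data.frame(center_cm1 = 1603, strength = S, damping_cm1 = 25),
      2.1, c(1603))
    stk <- layer_stack(layer(1), layer(4, 10), layer(m))
    normalized_spectrum(tip, stk, si, 1603)$phi_diff_deg
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("sphere_profile: background limit, symmetry, sphere narrower than disc", {
  tip <- default_tip()
  bg <- sin_d2o_stack()
  x <- seq(-800, 800, by = 50)
  ps <- sphere_profile(tip, 660, 2.1 + 0.02i, bg, x, wavenumber = 1603)
  bgv <- demodulate(tip, bg, 1603)
  far <- ps[abs(ps$offset) > 700, ]
  expect_equal(far$phi_n_deg, rep(bgv$phi_n, nrow(far)), tolerance = 1e-10)
  expect_equal(ps$phi_n_deg, rev(ps$phi_n_deg), tolerance = 1e-9)
  expect_equal(ps$offset[which.max(abs(ps$phi_n_deg - bgv$phi_n))], 0)

  pd <- sphere_profile(tip, 660, 2.1 + 0.02i, bg, x, wavenumber = 1603,
                       shape = "disc")
  expect_lt(profile_fwhm_numeric(ps$offset, ps$phi_n_deg),
            profile_fwhm_numeric(pd$offset, pd$phi_n_deg))

  expect_error(sphere_profile(tip, 660, 2.1, bg, c(-100, 0, 50)), "symmetric")
})

test_that("constructors enforce the domain invariants", {
  expect_error(tip_model(apex_radius_r = 400), "spheroid_length_L")
  expect_error(tip_model(g_factor = 2.5), "g_factor")
  expect_error(tip_model(min_height = -1), "min_height")
  expect_error(layer(1, -5), "thickness")
  expect_error(layer(1 - 0.5i), "passive")
  expect_error(layer_stack(layer(1)), "at least 2")
  expect_error(layer_stack(layer(1), layer(2, 10)), "semi-infinite")
  expect_error(layer_stack(layer(1), layer(2), layer(3)),
               "only the first and last")
  expect_warning(layer_stack(layer(5), layer(2)), "ambient")
})
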