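test_that("rectangular-duct series: square-channel factor and truncation error", {
  expect_equal(duct_correction_factor(1, 200), 0.421731, tolerance = 1e-5)
  expect_equal(duct_correction_factor(1, 2), duct_correction_factor(1, 200),
               tolerance = 1e-3)
  # the two-term truncation error is of order 1e-4 at the square aspect and
  # below 1e-3 across the aspect range
  for (a in seq(0.1, 1, by = 0.1)) {
    rel <- abs(duct_correction_factor(a, 2) / duct_correction_factor(a, 200) - 1)
    expect_lt(rel, 1e-3)
  }
  rel_sq <- abs(duct_correction_factor(1, 2) / duct_correction_factor(1, 200) - 1)
  expect_lt(rel_sq, 1e-3)
  expect_gt(rel_sq, 1e-5)   # of order 1e-4: real truncation, not noise
})

test_that("wide-slot limit of the duct flow rate", {
  g <- channel_geometry(l = 1e-3, w = 1e-2, h = 10e-6)
  Q <- rect_channel_flow_rate(g, dp = 100, mu = 1e-3, n_terms = 50)
  expect_equal(Q, g$w * g$h^3 * 100 / (12 * 1e-3 * g$l), tolerance = 1e-3)
})

test_that("full duct series is symmetric under swapping width and height", {
  g1 <- channel_geometry(l = 1e-3, w = 70e-6, h = 40e-6)
  g2 <- channel_geometry(l = 1e-3, w = 40e-6, h = 70e-6)
  Q1 <- rect_channel_flow_rate(g1, 10, 1e-3, n_terms = 200)
  Q2 <- rect_channel_flow_rate(g2, 10, 1e-3, n_terms = 200)
  expect_equal(Q1, Q2, tolerance = 1e-10)
})

test_that("hydraulic resistance: linearity and proportionality", {
  g <- channel_geometry(l = 250e-6, w = 100e-6, h = 100e-6)
  R1 <- hydraulic_resistance(g, mu = 1e-3)
  expect_equal(1 / rect_channel_flow_rate(g, 1, 1e-3, 20), R1)
  expect_equal(7 / rect_channel_flow_rate(g, 7, 1e-3, 20), R1)
  g2 <- channel_geometry(l = 500e-6, w = 100e-6, h = 100e-6)
  expect_equal(hydraulic_resistance(g2, mu = 1e-3), 2 * R1)
  # brute-force dp/Q oracle
  Q <- rect_channel_flow_rate(g, dp = 3.7, mu = 1e-3, n_terms = 200)
  expect_equal(hydraulic_resistance(g, 1e-3, n_terms = 200), 3.7 / Q)
})

test_that("Carreau-Yasuda viscosity: limits, monotonicity, mid-point value", {
  expect_equal(carreau_yasuda_viscosity(0, blood), 22e-3)
  expect_equal(carreau_yasuda_viscosity(1e9, blood), 2.2e-3, tolerance = 1e-3)
  # gamma = 1/lambda: mu = mu_inf + (mu0 - mu_inf) 2^((n-1)/a)
  expect_equal(carreau_yasuda_viscosity(1 / blood$lam, blood),
               2.2e-3 + 19.8e-3 * 2^((0.392 - 1) / 0.644))
  g <- 10^seq(-3, 5, length.out = 50)
  mu <- carreau_yasuda_viscosity(g, blood)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu <= 22e-3 & mu >= 2.2e-3))
  expect_error(carreau_yasuda_viscosity(-1, blood), ">= 0")
})

test_that("local shear rate solves the stress balance (Newton vs bisection oracle)", {
  w <- 100e-6; l <- 500e-6
  for (dp in c(5, 50, 500)) {
    for (z in c(0, 10e-6, 25e-6, 49e-6)) {
      g <- local_shear_rate(z, dp, l, w, blood)
      ts <- (dp / l) * (w / 2 - z)
      expect_equal(g * carreau_yasuda_viscosity(g, blood), ts, tolerance = 1e-8)
      expect_equal(g, bisect_shear(ts, blood), tolerance = 1e-8)
    }
  }
  # centreline: zero stress, zero rate
  expect_equal(local_shear_rate(w / 2, 100, l, w, blood), 0)
  # Newtonian limit: closed form
  pn <- carreau_yasuda(mu0 = 1e-3, mu_inf = 1e-3, lam = 0, a = 1, n = 1)
  expect_equal(local_shear_rate(10e-6, 100, l, w, pn),
               (100 / l) * (w / 2 - 10e-6) / 1e-3, tolerance = 1e-10)
})

test_that("Newtonian profile reproduces the plane Poiseuille parabola", {
  g <- channel_geometry(500e-6, 100e-6, x_m = 400e-6)
  pn <- carreau_yasuda(mu0 = 1e-3, mu_inf = 1e-3, lam = 0, a = 1, n = 1)
  dp <- 50
  pr <- velocity_profile_cy(g, dp, pn, n_points = 1001)
  exact <- dp * pr$z * (g$w - pr$z) / (2 * 1e-3 * g$l)
  expect_lt(max(abs(pr$u - exact)) / max(exact), 1e-3)
  expect_equal(attr(pr, "u_max"), dp * g$w^2 / (8 * 1e-3 * g$l), tolerance = 1e-3)
  expect_equal(attr(pr, "u_max") / attr(pr, "u_mean"), 1.5, tolerance = 1e-3)
})

test_that("shear-thinning profile is symmetric, wall-zero, monotone, and flat-centered", {
  g <- channel_geometry(500e-6, 100e-6, x_m = 400e-6)
  pr <- velocity_profile_cy(g, 100, blood, n_points = 501)
  n <- nrow(pr)
  expect_equal(pr$u[1], 0)
  expect_equal(pr$u[n], 0)
  expect_equal(pr$u, rev(pr$u), tolerance = 1e-12)
  half <- pr$u[seq_len((n + 1) / 2)]
  expect_true(all(diff(half) >= -1e-12))
  # flatter than the Newtonian parabola
  expect_lt(attr(pr, "u_max") / attr(pr, "u_mean"), 1.5)
  expect_gt(attr(pr, "u_max") / attr(pr, "u_mean"), 1.0)
})

test_that("mean-velocity inversion recovers the Newtonian closed form", {
  g <- channel_geometry(500e-6, 100e-6, x_m = 400e-6)
  pn <- carreau_yasuda(mu0 = 1e-3, mu_inf = 1e-3, lam = 0, a = 1, n = 1)
  sol <- profile_for_mean_velocity(g, u_in = 0.01, p = pn)
  expect_equal(sol$dp, 12 * 1e-3 * g$l * 0.01 / g$w^2, tolerance = 2e-3)
  expect_equal(attr(sol$profile, "u_mean"), 0.01, tolerance = 1e-6)
})

test_that("blood pressure drop is bracketed by the Newtonian bounds", {
  g <- channel_geometry(500e-6, 100e-6, x_m = 400e-6)
  sol <- profile_for_mean_velocity(g, u_in = 0.01, p = blood)
  dp_lo <- 12 * 2.2e-3 * g$l * 0.01 / g$w^2
  dp_hi <- 12 * 22e-3 * g$l * 0.01 / g$w^2
  expect_gt(sol$dp, dp_lo)
  expect_lt(sol$dp, dp_hi)
  expect_equal(attr(sol$profile, "u_mean"), 0.01, tolerance = 1e-6)
})
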