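# field-level flow physics on reduced grids (the acceptance suite exercises
# the full published grids)

test_that("body-force-driven periodic channel converges to the parabola at order ~2", {
  # periodic along x, walls along y; nu fixed, force scaled to keep u_max equal
  l2_err <- function(ny) {
    nx <- 8L
    mask <- periodic_box_mask(c(nx, ny + 2L))
    wall <- arrayInd(seq_len(prod(mask$dims)), mask$dims)[, 2] %in% c(1L, ny + 2L)
    mask$role[wall] <- MF_ROLES[["wall"]]
    st <- new_sim_state(mask, lat2, unit_scales(1e-6, 1e-6),
                        periodic = c(TRUE, FALSE))
    tau <- 0.8
    nu <- viscosity_from_tau(tau)
    u_max <- 0.02
    Fb <- 8 * nu * u_max / ny^2
    st <- initialize_equilibrium(st, rho = 1, tau = tau)
    st$body_force[1, 1] <- Fb
    st <- run_steady(st, convergence_monitor(400, 1e-10), max_steps = 120000)
    st <- refresh_macroscopic(st)
    pr <- matrix(st$u[, 1], mask$dims[1], mask$dims[2])[4, 2:(ny + 1)]
    exact <- u_max * (4 * ((seq_len(ny) - 0.5) / ny) * (1 - (seq_len(ny) - 0.5) / ny))
    sqrt(mean((pr - exact)^2)) / u_max
  }
  ny <- c(8L, 16L, 32L)
  err <- vapply(ny, l2_err, 0)
  expect_true(all(diff(err) < 0))
  slope <- -coef(lm(log(err) ~ log(ny)))[2]
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
})

test_that("inlet/outlet driven channel develops the plane Poiseuille ratio 1.5", {
  st <- make_channel_state(nx = 100, ny = 20, u_in = 0.02, tau = 1.0, dt = 5e-6)
  st <- run_steady(st, convergence_monitor(500, 1e-7), max_steps = 40000)
  st <- refresh_macroscopic(st)
  pr <- extract_profile(st$u[, 1], st$mask, 80e-6)
  expect_equal(max(pr$value) / mean(pr$value), 1.5, tolerance = 0.01)
  # mass conservation: inlet flux equals outlet flux at steady state
  co <- arrayInd(seq_len(prod(st$mask$dims)), st$mask$dims)
  flux <- function(ix) {
    sel <- co[, 1] == ix & st$mask$role == MF_ROLES[["fluid"]]
    sum(st$rho[sel, 1] * st$u[sel, 1])
  }
  expect_equal(flux(2L), flux(st$mask$dims[1] - 1L), tolerance = 1e-3)
})

test_that("velocity inlet with zero speed degenerates to a resting no-slip wall", {
  st <- make_channel_state(nx = 12, ny = 6, u_in = 0, tau = 0.8)
  set.seed(77)
  m0 <- total_mass(st)
  st <- lbm_advance(st, 2000)
  st <- refresh_macroscopic(st)
  expect_lt(max(abs(st$u)), 1e-10)
  expect_equal(total_mass(st), m0, tolerance = 1e-12)
})

test_that("Carreau-Yasuda coupling yields a flat-centered profile and wall-low tau", {
  # reduced blood channel: half-scale grid, same physics
  cfg <- load_config(example_config("flow_blood"))
  cfg$solver$dx <- 4e-6
  cfg$geometry <- channel_geometry(200e-6, 80e-6, x_m = 160e-6)
  res <- run_flow_case(cfg, "2d", max_steps = 30000, keep_state = TRUE)
  expect_gt(res$report$flatness, 1.0)
  expect_lt(res$report$flatness, 1.5)
  st <- res$state
  tau_f <- matrix(st$tau[[1]], st$mask$dims[1], st$mask$dims[2])
  mid_x <- round(st$mask$dims[1] / 2)
  expect_lt(tau_f[mid_x, 2], tau_f[mid_x, round(st$mask$dims[2] / 2)])
  # 1D semi-analytic cross-check away from walls
  sol <- profile_for_mean_velocity(cfg$geometry, cfg$driving$u_in, cfg$fluid$cy)
  pr2 <- res$profile
  u1 <- approx(sol$profile$z, sol$profile$u, xout = pr2$z)$y
  interior <- pr2$z > 0.15 * cfg$geometry$w & pr2$z < 0.85 * cfg$geometry$w
  expect_lt(max(abs(pr2$u[interior] - u1[interior]) / max(u1)), 0.05)
})

test_that("3D channel flow peaks higher than 2D at the same mean inlet speed", {
  cfg <- load_config(example_config("flow_blood"))
  cfg$solver$dx <- 8e-6
  cfg$geometry <- channel_geometry(240e-6, 80e-6, h = 80e-6, x_m = 200e-6)
  r2 <- run_flow_case(cfg, "2d", max_steps = 25000)
  r3 <- run_flow_case(cfg, "3d", max_steps = 25000)
  expect_gt(max(r3$profile$u), max(r2$profile$u))
})
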