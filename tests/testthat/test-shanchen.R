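make_two_comp <- function(dims = c(16, 10), G = 0.8, tau = 1,
                          alpha = NULL, rho_tot = 1) {
  box <- periodic_box_mask(dims)
  st <- new_sim_state(box, lat2, unit_scales(1e-6, 1e-6), ncomp = 2,
                      periodic = c(TRUE, TRUE), G = G)
  if (is.null(alpha)) alpha <- rep(0.5, prod(dims))
  initialize_equilibrium(st, rho = cbind(rho_tot * alpha, rho_tot * (1 - alpha)),
                         tau = tau)
}

test_that("Shan-Chen force vanishes for zero coupling and uniform fields", {
  x <- arrayInd(seq_len(160), c(16, 10))[, 1]
  a <- ifelse(x <= 8, 0.9, 0.1)
  st0 <- make_two_comp(G = 0, alpha = a)
  expect_equal(max(abs(unlist(shan_chen_force(st0)))), 0)
  expect_error(shan_chen_force(initialize_equilibrium(
    new_sim_state(periodic_box_mask(c(4, 4)), lat2, unit_scales(1e-6, 1e-6),
                  ncomp = 1, periodic = c(TRUE, TRUE), G = 1), rho = 1)),
    "two components")
  stu <- make_two_comp(G = 1.2, alpha = NULL)   # uniform mixture
  expect_equal(max(abs(unlist(shan_chen_force(stu)))), 0, tolerance = 1e-14)
})

test_that("interfacial forces are antisymmetric and inject zero net momentum", {
  x <- arrayInd(seq_len(160), c(16, 10))[, 1]
  a <- ifelse(x <= 8, 0.95, 0.05)
  st <- make_two_comp(G = 0.9, alpha = a)
  Fs <- shan_chen_force(st)
  tot <- Fs[[1]] + Fs[[2]]
  expect_equal(sum(tot[, 1]), 0, tolerance = 1e-12)
  expect_equal(sum(tot[, 2]), 0, tolerance = 1e-12)
  # mutual repulsion across the interface: component A (left majority) is
  # pushed left, component B (right majority) is pushed right
  expect_lt(max(Fs[[1]][x == 8, 1]), 0)
  expect_gt(min(Fs[[2]][x == 9, 1]), 0)
})

test_that("a uniform body force accelerates a periodic component at F/rho per step", {
  box <- periodic_box_mask(c(10, 10))
  st <- new_sim_state(box, lat2, unit_scales(1e-6, 1e-6), ncomp = 1,
                      periodic = c(TRUE, TRUE))
  st <- initialize_equilibrium(st, rho = 1, tau = 0.9)
  st$body_force[1, 1] <- 3e-6
  n <- 200
  st <- lbm_advance(st, n)
  m <- macroscopic(st$f[[1]], lat2)
  # velocity-shift forcing adds exactly F to the bare momentum each step
  expect_equal(mean(m$u[, 1]), 3e-6 * n, tolerance = 1e-9)
})

test_that("swapping components mirrors the concentration field exactly", {
  set.seed(9)
  x <- arrayInd(seq_len(160), c(16, 10))[, 1]
  a <- 0.5 + 0.4 * sin(2 * pi * x / 16)
  st <- make_two_comp(G = 0.8, tau = 0.7, alpha = a)
  sw <- st
  sw$f <- st$f[c(2, 1)]
  sw$tau <- st$tau[c(2, 1)]
  sw$bc_rho <- st$bc_rho[, c(2, 1)]
  st <- lbm_advance(st, 50)
  sw <- lbm_advance(sw, 50)
  expect_identical(st$f[[1]], sw$f[[2]])
  expect_identical(st$f[[2]], sw$f[[1]])
})

test_that("pair diffusivity is positive without coupling and decreases with G", {
  d0 <- measure_pair_diffusivity(0.7, 0)
  expect_equal(d0, (0.7 - 0.5) / 3, tolerance = 0.02)
  d1 <- measure_pair_diffusivity(0.7, 0.3)
  d2 <- measure_pair_diffusivity(0.7, 0.5)
  expect_true(d1 < d0 && d2 < d1)
})

test_that("relaxation-time calibration realizes a target coupled diffusivity", {
  cal <- calibrate_mixing_tau(3e-3, G = 0.6, rho_tot = 1)
  expect_equal(cal$D_lat, 3e-3, tolerance = 6e-3)
  expect_gt(cal$tau, 0.5)
  m <- measure_pair_diffusivity(cal$tau, 0.6, nsteps = 1500L)
  expect_equal(m, 3e-3, tolerance = 0.02)
})

test_that("increasing G from the mixing to the droplet value sharpens the interface", {
  # steady flat interface width (0.1-0.9 alpha transition) at rho_tot = 2
  width_at <- function(G) {
    nx <- 64
    box <- periodic_box_mask(c(nx, 6))
    st <- new_sim_state(box, lat2, unit_scales(1e-6, 1e-6), ncomp = 2,
                        periodic = c(TRUE, TRUE), G = G)
    x <- arrayInd(seq_len(nx * 6), c(nx, 6))[, 1]
    a <- ifelse(x > nx / 4 & x <= 3 * nx / 4, 0.91, 0.09)
    st <- initialize_equilibrium(st, rho = cbind(2 * a, 2 * (1 - a)), tau = 1.7)
    st <- lbm_advance(st, 3000)
    st <- refresh_macroscopic(st)
    al <- st$rho[, 1] / rowSums(st$rho)
    row1 <- al[seq_len(nx)]
    sum(row1 > 0.1 & row1 < 0.9)
  }
  w_mix <- width_at(0.95)   # weakly segregating at this density
  w_drop <- width_at(1.1)
  expect_lt(w_drop, w_mix)
  expect_gte(w_drop, 1)
})

test_that("droplet initialization places the slug with wall films and one component", {
  cfg <- load_config(example_config("droplet_bifurcation"))
  # a short, unconverged carrier run is fine for checking the initialization
  carrier <- suppressWarnings(precompute_carrier_flow(cfg, "2d", max_steps = 400))
  st <- init_droplet(carrier, cfg)
  st <- refresh_macroscopic(st)
  alpha <- st$rho[, 2] / rowSums(pmax(st$rho, 1e-300))
  tr <- droplet_track(alpha, carrier$mask)
  expect_equal(tr$n_components, 1L)
  expect_equal(tr$length_um, 200, tolerance = 2 * 2.5 / 200)  # within 2 cells
  expect_identical(tr$branch, "inlet")
  # droplet mass approximates slug volume x (1 - floor) x density
  j <- attr(carrier$mask, "junction")
  flo <- cfg$minority_floor
  dl_cells <- round(cfg$droplet$dl / carrier$scales$dx)
  slug_cells <- dl_cells * (j$nw - 2 * cfg$droplet$gap_cells)
  expect_equal(attr(st, "droplet_mass0"),
               slug_cells * carrier$rho0 * (1 - flo) +
                 (sum(carrier$mask$role == 0) - slug_cells) * carrier$rho0 * flo,
               tolerance = 0.05)
  # film rows adjacent to the walls are carrier-majority
  co <- arrayInd(seq_len(prod(carrier$mask$dims)), carrier$mask$dims)
  film <- co[, 2] %in% c(j$ylo + 1L, j$yhi + 1L) & carrier$mask$role == 0 &
    co[, 1] <= j$nl + 1L
  expect_true(all(alpha[film] < 0.5))
})
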