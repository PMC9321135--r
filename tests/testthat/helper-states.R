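# shared builders and independent oracles for the solver tests

lat2 <- make_lattice("D2Q9")
lat3 <- make_lattice("D3Q19")

# small driven channel state (inlet plug / pressure outlet)
make_channel_state <- function(nx = 20, ny = 10, u_in = 0.03, tau = 0.8,
                               dx = 1e-6, dt = 1e-6) {
  g <- channel_geometry(nx * dx, ny * dx, x_m = nx * dx * 0.8)
  sc <- unit_scales(dx, dt)
  mask <- build_channel_mask(g, sc, 2)
  st <- new_sim_state(mask, lat2, sc, ncomp = 1, outlet_bc = "pressure")
  st$bc_u[mask$role == MF_ROLES[["inlet"]], 1] <- u_in
  initialize_equilibrium(st, rho = 1, tau = tau)
}

# random perturbation of the populations on fluid cells (kept positive)
perturb <- function(state, amp = 0.02) {
  for (s in seq_len(state$ncomp)) {
    n <- length(state$fluid) * state$lattice$q
    state$f[[s]][state$fluid, ] <- state$f[[s]][state$fluid, ] *
      (1 + amp * (runif(n) - 0.5))
  }
  state
}

# moment oracles by explicit summation
oracle_density <- function(f) apply(f, 1, sum)
oracle_momentum <- function(f, lattice) {
  t(apply(f, 1, function(fi) colSums(fi * lattice$c)))
}

# plane Poiseuille profile at cell centres (lattice units), width ny cells,
# mean velocity u_mean
poiseuille_profile <- function(ny, u_mean) {
  z <- (seq_len(ny) - 0.5) / ny
  6 * u_mean * z * (1 - z)
}

# bisection oracle for the shear-rate stress balance
bisect_shear <- function(ts, p, tol = 1e-14) {
  if (ts <= 0) return(0)
  f <- function(g) g * carreau_yasuda_viscosity(g, p) - ts
  lo <- 0; hi <- 10 * ts / p$mu_inf
  while (hi - lo > tol * max(hi, 1)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

blood <- carreau_yasuda()
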