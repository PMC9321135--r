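#' Create a simulation state
#'
#' Allocates populations, macroscopic fields and boundary-value arrays for a
#' (possibly multi-component) lattice-Boltzmann run on a rasterized domain.
#' Populations are stored as one \code{ncell x q} matrix per component; cells
#' are indexed in x-fastest order matching the mask.
#'
#' @param mask an \code{"mf_mask"} from \code{\link{build_channel_mask}} /
#'   \code{\link{build_bifurcation_mask}}, or any mask (e.g. an all-fluid
#'   periodic box built with \code{\link{periodic_box_mask}}).
#' @param lattice an \code{"mf_lattice"}; its dimension must match the mask.
#' @param scales a \code{\link{unit_scales}}.
#' @param ncomp number of fluid components (1 or 2).
#' @param outlet_bc \code{"pressure"} (anti-bounce-back on the prescribed
#'   outlet density) or \code{"velocity"} (bounce-back with momentum
#'   correction at the outlet, used by the mixing case).
#' @param periodic logical vector per axis; periodic axes wrap the streaming
#'   step instead of applying boundary rules.
#' @param G Shan-Chen inter-component coupling coefficient (lattice units).
#' @return object of class \code{"mf_state"}.
#' @export
new_sim_state <- function(mask, lattice, scales, ncomp = 1L,
                          outlet_bc = c("pressure", "velocity"),
                          periodic = rep(FALSE, lattice$d), G = 0) {
  outlet_bc <- match.arg(outlet_bc)
  stopifnot(inherits(mask, "mf_mask"), inherits(lattice, "mf_lattice"))
  if (length(mask$dims) != lattice$d) stop("mask dimensionality does not match the lattice")
  ncell <- prod(mask$dims)
  links <- build_links(mask, lattice, outlet_bc, periodic)
  st <- structure(list(
    mask = mask, lattice = lattice, scales = scales,
    ncomp = as.integer(ncomp), outlet_bc = outlet_bc, periodic = periodic,
    G = G,
    f = replicate(ncomp, matrix(0, ncell, lattice$q), simplify = FALSE),
    tau = replicate(ncomp, rep(1, ncell), simplify = FALSE),
    body_force = matrix(0, lattice$d, ncomp),
    bc_rho = matrix(1, ncell, ncomp),
    bc_u = matrix(0, ncell, lattice$d),
    abb_local = FALSE,
    cy = NULL,
    links = links,
    fluid = which(mask$role == MF_ROLES[["fluid"]]),
    step = 0L), class = "mf_state")
  st
}

#' Periodic box mask (all cells fluid)
#'
#' Convenience mask for closed/periodic test domains and calibration runs.
#' @param dims integer grid dimensions.
#' @param dx cell size (m).
#' @export
periodic_box_mask <- function(dims, dx = 1e-6) {
  new_mask(rep(MF_ROLES[["fluid"]], prod(dims)), as.integer(dims), dx)
}

# link-type codes shared with the compiled stepper
MF_LT <- c(pull = 0L, wall = 1L, inlet = 2L, abb = 3L, vout = 4L)

# per-cell per-direction pull source index and link type
build_links <- function(mask, lattice, outlet_bc, periodic) {
  gd <- mask$dims; d <- lattice$d; q <- lattice$q
  ncell <- prod(gd)
  coords <- arrayInd(seq_len(ncell), gd)
  nbr <- matrix(0L, ncell, q)
  lt <- matrix(0L, ncell, q)
  role <- mask$role
  for (i in seq_len(q)) {
    src <- coords
    for (a in seq_len(d)) {
      s <- coords[, a] - lattice$c[i, a]
      if (periodic[a]) s <- ((s - 1L) %% gd[a]) + 1L
      else s <- pmin(pmax(s, 1L), gd[a])  # clamped; only reached from border cells
      src[, a] <- s
    }
    idx <- src[, 1]
    mult <- 1L
    for (a in seq_len(d - 1L)) {
      mult <- mult * gd[a]
      idx <- idx + (src[, a + 1L] - 1L) * mult
    }
    nbr[, i] <- idx
    r <- role[idx]
    lt[, i] <- ifelse(r == MF_ROLES[["fluid"]], MF_LT[["pull"]],
               ifelse(r == MF_ROLES[["wall"]], MF_LT[["wall"]],
               ifelse(r == MF_ROLES[["inlet"]], MF_LT[["inlet"]],
                      if (outlet_bc == "pressure") MF_LT[["abb"]] else MF_LT[["vout"]])))
  }
  list(nbr = nbr, lt = lt)
}

#' Equilibrium populations
#'
#' Second-order truncated Maxwellian,
#' \deqn{f_i^{eq} = w_i \rho \left[1 + \frac{u\cdot c_i}{c_s^2}
#'   + \frac{(u \cdot c_i)^2}{2 c_s^4} - \frac{u\cdot u}{2 c_s^2}\right],}
#' whose moments recover \eqn{\sum f^{eq} = \rho} and
#' \eqn{\sum c_i f^{eq} = \rho u} exactly.
#'
#' @param rho density vector (one per cell, lattice units).
#' @param u velocity matrix, \code{length(rho) x d} (lattice units).
#' @param lattice an \code{"mf_lattice"}.
#' @return \code{length(rho) x q} matrix of equilibrium populations.
#' @export
equilibrium <- function(rho, u, lattice) {
  if (is.null(dim(u))) u <- matrix(u, nrow = length(rho))
  usq <- rowSums(u * u)
  feq <- matrix(0, length(rho), lattice$q)
  for (i in seq_len(lattice$q)) {
    cu <- as.vector(u %*% lattice$c[i, ])
    feq[, i] <- lattice$w[i] * rho * (1 + 3 * cu + 4.5 * cu^2 - 1.5 * usq)
  }
  feq
}

#' Macroscopic moments of a population set
#'
#' \eqn{\rho = \sum_i f_i}, \eqn{\rho u = \sum_i c_i f_i} (plus half of any
#' acting force when \code{force} is supplied, the trapezoidal force shift).
#'
#' @param f \code{ncell x q} population matrix.
#' @param lattice an \code{"mf_lattice"}.
#' @param force optional \code{ncell x d} force density to fold into the
#'   velocity moment.
#' @return list with \code{rho} (vector) and \code{u} (\code{ncell x d}).
#' @export
macroscopic <- function(f, lattice, force = NULL) {
  rho <- rowSums(f)
  mom <- f %*% lattice$c
  if (!is.null(force)) mom <- mom + force / 2
  u <- mom / pmax(rho, .Machine$double.xmin)
  list(rho = rho, u = u)
}

#' Local shear strain rate from the non-equilibrium populations
#'
#' The strain-rate tensor is available locally in a lattice-Boltzmann fluid,
#' without finite differences, from the second moment of the non-equilibrium
#' part:
#' \deqn{S_{\alpha\beta} = -\frac{1}{2 \rho c_s^2 \tau}
#'   \sum_i c_{i\alpha} c_{i\beta} (f_i - f_i^{eq}),}
#' with the scalar rate \eqn{\dot\gamma = \sqrt{2 S : S}}.
#'
#' @param state an \code{"mf_state"} (component 1 is used).
#' @param si if \code{TRUE} (default) convert to 1/s using the state's time
#'   scale; otherwise return the lattice-unit rate.
#' @return numeric vector of shear rates per cell (zero on non-fluid cells).
#' @export
strain_rate_local <- function(state, si = TRUE) {
  lat <- state$lattice
  f <- state$f[[1]]
  m <- macroscopic(f, lat)
  feq <- equilibrium(m$rho, m$u, lat)
  fneq <- f - feq
  d <- lat$d
  ssum <- 0
  for (a in seq_len(d)) for (b in seq_len(d)) {
    Sab <- fneq %*% (lat$c[, a] * lat$c[, b])
    Sab <- -Sab / (2 * pmax(m$rho, .Machine$double.xmin) * lat$cs2 * state$tau[[1]])
    ssum <- ssum + Sab^2
  }
  g <- sqrt(2 * ssum)
  g[state$mask$role != MF_ROLES[["fluid"]]] <- 0
  if (si) as.vector(g) / state$scales$dt else as.vector(g)
}

#' Update the relaxation-time field from a Carreau-Yasuda law
#'
#' Converts the local effective viscosity \eqn{\mu_{eff}(\dot\gamma)/\rho} to
#' lattice units and to a relaxation time, clamping into the stable window.
#'
#' @param gamma_dot shear-rate field (1/s).
#' @param p \code{\link{carreau_yasuda}} parameters.
#' @param rho_si fluid density (kg/m^3).
#' @param scales \code{\link{unit_scales}}.
#' @param tau_bounds clamp interval for the relaxation time.
#' @return relaxation-time vector (lattice units).
#' @export
update_tau_carreau_yasuda <- function(gamma_dot, p, rho_si, scales,
                                      tau_bounds = c(0.5 + 1e-6, 3.5)) {
  nu <- carreau_yasuda_viscosity(gamma_dot, p) / rho_si
  tau <- tau_from_viscosity(si_to_lattice(nu, "kinematic-viscosity", scales))
  pmin(pmax(tau, tau_bounds[1]), tau_bounds[2])
}

# Shan-Chen pseudopotential of the partner component as seen across each link,
# honouring boundary cells: walls are inert (psi = 0), inlets carry their
# prescribed composition, outlets mirror the local fluid value.
.psi_across <- function(state, comp) {
  lat <- state$lattice
  rho <- rowSums(state$f[[comp]])
  psi <- matrix(0, length(rho), lat$q)  # psi of `comp` at x + c_i, column i
  for (i in seq_len(lat$q)) {
    fwd <- state$links$nbr[, lat$opp[i]]     # x + c_i
    tf <- state$links$lt[, lat$opp[i]]
    v <- rho[fwd]
    v[tf == MF_LT[["wall"]]] <- 0
    v[tf == MF_LT[["inlet"]]] <- state$bc_rho[fwd, comp][tf == MF_LT[["inlet"]]]
    loc <- tf == MF_LT[["abb"]] | tf == MF_LT[["vout"]]
    v[loc] <- rho[loc]
    psi[, i] <- v
  }
  psi
}

#' Shan-Chen inter-component force
#'
#' Pseudopotential force with \eqn{\psi = \rho} and inter-component coupling
#' only:
#' \deqn{F_\sigma(x) = -G\, \psi_\sigma(x) \sum_i w_i\,
#'   \psi_{\bar\sigma}(x + c_i)\, c_i.}
#' With \code{G = 0} or uniform fields the force vanishes identically (the
#' lattice first moment of the weights is zero).
#'
#' @param state a two-component \code{"mf_state"}.
#' @return list of two \code{ncell x d} force matrices (lattice units).
#' @export
shan_chen_force <- function(state) {
  lat <- state$lattice
  if (state$ncomp != 2L) stop("Shan-Chen force needs two components")
  out <- vector("list", 2L)
  for (comp in 1:2) {
    other <- 3L - comp
    psi_o <- .psi_across(state, other)
    rho_s <- rowSums(state$f[[comp]])
    Fm <- matrix(0, length(rho_s), lat$d)
    for (a in seq_len(lat$d)) {
      Fm[, a] <- -state$G * rho_s * as.vector(psi_o %*% (lat$w * lat$c[, a]))
    }
    Fm[state$mask$role != MF_ROLES[["fluid"]], ] <- 0
    out[[comp]] <- Fm
  }
  out
}

# total per-component force: Shan-Chen + constant body force
component_forces <- function(state) {
  ncell <- prod(state$mask$dims)
  forces <- replicate(state$ncomp, matrix(0, ncell, state$lattice$d), simplify = FALSE)
  if (state$G != 0 && state$ncomp == 2L) forces <- shan_chen_force(state)
  for (comp in seq_len(state$ncomp)) {
    bf <- state$body_force[, comp]
    if (any(bf != 0)) {
      fl <- state$fluid
      forces[[comp]][fl, ] <- sweep(forces[[comp]][fl, , drop = FALSE], 2, bf, `+`)
    }
  }
  forces
}

#' One BGK collide-and-stream step (reference implementation)
#'
#' Advances the state by one time step: computes moments, optional Shan-Chen
#' and body forces (velocity-shift forcing), relaxes each population set
#' toward its equilibrium at the common mixture velocity, and streams with the
#' boundary-condition family (halfway bounce-back walls, velocity bounce-back
#' inlets, anti-bounce-back pressure outlets). This pure-R path defines the
#' update rule; the compiled stepper used by \code{\link{run_steady}} is
#' checked against it step for step.
#'
#' @param state an \code{"mf_state"}.
#' @return the advanced state; fields \code{rho} (matrix per component) and
#'   \code{u} (barycentric, half-force corrected) are refreshed.
#' @export
collide_and_stream <- function(state) {
  lat <- state$lattice
  q <- lat$q; d <- lat$d
  ncell <- prod(state$mask$dims)
  nonfluid <- state$mask$role != MF_ROLES[["fluid"]]

  rho <- matrix(0, ncell, state$ncomp)
  mom <- replicate(state$ncomp, matrix(0, ncell, d), simplify = FALSE)
  for (s in seq_len(state$ncomp)) {
    rho[, s] <- rowSums(state$f[[s]])
    mom[[s]] <- state$f[[s]] %*% lat$c
  }
  forces <- component_forces(state)

  # common (mixture) velocity weighted by rho/tau
  num <- matrix(0, ncell, d); den <- numeric(ncell)
  for (s in seq_len(state$ncomp)) {
    num <- num + mom[[s]] / state$tau[[s]]
    den <- den + rho[, s] / state$tau[[s]]
  }
  u_common <- num / pmax(den, .Machine$double.xmin)

  # Carreau-Yasuda viscosity coupling (single component)
  if (!is.null(state$cy)) {
    g <- strain_rate_local(state, si = TRUE)
    state$tau[[1]] <- update_tau_carreau_yasuda(g, state$cy$params, state$cy$rho_si, state$scales)
  }

  fpost <- vector("list", state$ncomp)
  for (s in seq_len(state$ncomp)) {
    u_eq <- u_common + state$tau[[s]] * forces[[s]] / pmax(rho[, s], .Machine$double.xmin)
    feq <- equilibrium(rho[, s], u_eq, lat)
    fpost[[s]] <- state$f[[s]] - (state$f[[s]] - feq) / state$tau[[s]]
  }

  # barycentric velocity used by anti-bounce-back outlets
  rho_tot <- rowSums(rho)
  mtot <- Reduce(`+`, mom)
  u_b <- mtot / pmax(rho_tot, .Machine$double.xmin)
  ubsq <- rowSums(u_b * u_b)

  for (s in seq_len(state$ncomp)) {
    fnew <- matrix(0, ncell, q)
    fp <- fpost[[s]]
    for (i in seq_len(q)) {
      io <- lat$opp[i]
      src <- state$links$nbr[, i]
      tf <- state$links$lt[, i]
      col <- fp[src, i]                               # plain pull
      wll <- tf == MF_LT[["wall"]]
      col[wll] <- fp[wll, io]                         # halfway bounce-back
      inl <- tf == MF_LT[["inlet"]]
      if (any(inl)) {
        cu <- as.vector(state$bc_u[src, , drop = FALSE] %*% lat$c[i, ])
        col[inl] <- fp[inl, io] + 2 * lat$w[i] * state$bc_rho[src, s][inl] * cu[inl] / lat$cs2
      }
      ab <- tf == MF_LT[["abb"]]
      if (any(ab)) {
        cu <- as.vector(u_b %*% lat$c[i, ])
        # abb_local: prescribe the total outlet density and let the local
        # composition set the per-component share (free outflow mixture);
        # otherwise pin the prescribed per-component densities
        rho_tgt <- if (isTRUE(state$abb_local) && state$ncomp > 1L) {
          share <- ifelse(rho_tot > 0, rho[, s] / rho_tot, 1 / state$ncomp)
          rowSums(state$bc_rho[src, , drop = FALSE]) * share
        } else {
          state$bc_rho[src, s]
        }
        col[ab] <- -fp[ab, io] + 2 * lat$w[i] * rho_tgt[ab] *
          (1 + cu[ab]^2 / (2 * lat$cs2^2) - ubsq[ab] / (2 * lat$cs2))
      }
      vo <- tf == MF_LT[["vout"]]
      if (any(vo)) {
        cu <- as.vector(state$bc_u[src, , drop = FALSE] %*% lat$c[i, ])
        col[vo] <- fp[vo, io] + 2 * lat$w[i] * rho[vo, s] * cu[vo] / lat$cs2
      }
      fnew[, i] <- col
    }
    fnew[nonfluid, ] <- 0
    state$f[[s]] <- fnew
  }

  ftot <- Reduce(`+`, forces)
  state$rho <- rho
  state$u <- (mtot + ftot / 2) / pmax(rho_tot, .Machine$double.xmin)
  state$u[nonfluid, ] <- 0
  state$step <- state$step + 1L
  state
}

#' Initialize populations at equilibrium
#'
#' @param state an \code{"mf_state"}.
#' @param rho per-component density: scalar, vector (per cell) or
#'   \code{ncell x ncomp} matrix (lattice units).
#' @param u initial velocity: vector of length d or \code{ncell x d}.
#' @param tau per-component relaxation time: scalar or list of per-cell
#'   vectors.
#' @export
initialize_equilibrium <- function(state, rho = 1, u = rep(0, state$lattice$d), tau = NULL) {
  ncell <- prod(state$mask$dims)
  if (is.null(dim(rho))) {
    rho <- matrix(rho, ncell, state$ncomp, byrow = length(rho) == state$ncomp)
  }
  if (is.null(dim(u))) u <- matrix(u, ncell, state$lattice$d, byrow = TRUE)
  for (s in seq_len(state$ncomp)) {
    r <- rho[, s]
    state$f[[s]] <- equilibrium(r, u, state$lattice)
    state$f[[s]][state$mask$role != MF_ROLES[["fluid"]], ] <- 0
    if (!is.null(tau)) {
      state$tau[[s]] <- rep(if (is.list(tau)) tau[[s]] else tau, length.out = ncell)
    }
  }
  state$rho <- rho
  state$u <- u
  state
}

#' Total mass per component over the fluid region
#' @param state an \code{"mf_state"}.
#' @export
total_mass <- function(state) {
  vapply(state$f, function(f) sum(f[state$fluid, ]), 0)
}

#' Mean kinetic-energy density over the fluid region (lattice units)
#' @param state an \code{"mf_state"}.
#' @export
mean_kinetic_energy <- function(state) {
  lat <- state$lattice
  rho_tot <- numeric(prod(state$mask$dims))
  mom <- matrix(0, prod(state$mask$dims), lat$d)
  for (s in seq_len(state$ncomp)) {
    rho_tot <- rho_tot + rowSums(state$f[[s]])
    mom <- mom + state$f[[s]] %*% lat$c
  }
  fl <- state$fluid
  mean(0.5 * rowSums(mom[fl, , drop = FALSE]^2) / pmax(rho_tot[fl], .Machine$double.xmin))
}
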