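#' Convergence monitor
#'
#' Steady state is declared when the relative change of the windowed mean
#' kinetic-energy density between successive windows falls below \code{tol}.
#'
#' @param window steps per monitoring window.
#' @param tol relative tolerance on the windowed change.
#' @export
convergence_monitor <- function(window = 1000L, tol = 1e-5) {
  stopifnot(window >= 1L, tol > 0)
  structure(list(window = as.integer(window), tol = tol), class = "mf_monitor")
}

# CY coupling descriptor consumed by the compiled stepper
.cy_cpp <- function(state) {
  if (is.null(state$cy)) return(NULL)
  p <- state$cy$params
  list(mu0 = p$mu0, mu_inf = p$mu_inf, lam = p$lam, a = p$a, n = p$n,
       rho_si = state$cy$rho_si, dt = state$scales$dt,
       nu_conv = state$scales$dt / state$scales$dx^2,
       tau_bounds = c(0.5 + 1e-6, 3.5),
       every = if (is.null(state$cy$every)) 1L else as.integer(state$cy$every))
}

#' Advance a state by a fixed number of steps (compiled path)
#'
#' Runs \code{nsteps} collide-and-stream updates through the compiled engine.
#' Equivalent to \code{nsteps} applications of
#' \code{\link{collide_and_stream}}.
#'
#' @param state an \code{"mf_state"}.
#' @param nsteps number of time steps.
#' @return the advanced state; attributes \code{ke} (mean kinetic energy,
#'   lattice units) and \code{mass} (per component) reflect the final step.
#' @export
lbm_advance <- function(state, nsteps) {
  res <- lbm_chunk_cpp(state$f, state$tau, state$bc_rho, state$bc_u,
                       state$links$nbr, state$links$lt, state$mask$role,
                       state$lattice$c * 1.0, state$lattice$w, state$lattice$opp,
                       state$G, state$body_force, as.integer(nsteps),
                       .cy_cpp(state), as.integer(isTRUE(state$abb_local)))
  if (isTRUE(res$diverged)) {
    stop(sprintf("numerical instability: non-finite population at cell %d (step ~%d)",
                 res$bad_cell, state$step))
  }
  state$f <- res$f
  state$tau <- res$tau
  state$step <- state$step + as.integer(nsteps)
  attr(state, "ke") <- res$ke
  attr(state, "mass") <- res$mass
  state
}

#' Run to steady state
#'
#' Iterates the compiled collide-and-stream engine (including any Shan-Chen
#' and Carreau-Yasuda coupling configured on the state) until the windowed
#' mean kinetic energy stabilizes, or the step budget is exhausted.
#'
#' @param state an \code{"mf_state"}.
#' @param monitor a \code{\link{convergence_monitor}}.
#' @param max_steps step budget.
#' @param min_windows minimum number of windows before convergence may be
#'   declared (guards against freak early matches while the flow develops).
#' @param verbose print telemetry per window.
#' @return the converged state; attributes \code{converged} (logical),
#'   \code{steps}, and \code{ke_history}.
#' @export
run_steady <- function(state, monitor = convergence_monitor(),
                       max_steps = 200000L, min_windows = 3L, verbose = FALSE) {
  ke_prev <- NA_real_
  history <- numeric(0)
  converged <- FALSE
  nwin <- 0L
  while (state$step < max_steps) {
    state <- lbm_advance(state, min(monitor$window, max_steps - state$step))
    ke <- attr(state, "ke")
    history <- c(history, ke)
    nwin <- nwin + 1L
    if (verbose) {
      message(sprintf("step %d: mean KE = %.6e", state$step, ke))
    }
    if (!is.na(ke_prev)) {
      ref <- max(abs(ke), .Machine$double.xmin)
      if (abs(ke - ke_prev) / ref < monitor$tol && nwin >= min_windows) {
        converged <- TRUE
        break
      }
    }
    ke_prev <- ke
  }
  attr(state, "converged") <- converged
  attr(state, "steps") <- state$step
  attr(state, "ke_history") <- history
  if (!converged) {
    warning(sprintf("steady-state run hit the step budget (%d) before converging", max_steps))
  }
  state
}

#' Refresh the macroscopic fields of a state
#'
#' Recomputes per-component densities and the barycentric velocity (with the
#' half-force shift when coupling forces act) from the current populations.
#' @param state an \code{"mf_state"}.
#' @return state with \code{rho} (ncell x ncomp) and \code{u} (ncell x d) set.
#' @export
refresh_macroscopic <- function(state) {
  lat <- state$lattice
  ncell <- prod(state$mask$dims)
  rho <- matrix(0, ncell, state$ncomp)
  mtot <- matrix(0, ncell, lat$d)
  for (s in seq_len(state$ncomp)) {
    rho[, s] <- rowSums(state$f[[s]])
    mtot <- mtot + state$f[[s]] %*% lat$c
  }
  forces <- component_forces(state)
  ftot <- Reduce(`+`, forces)
  rho_tot <- rowSums(rho)
  u <- (mtot + ftot / 2) / pmax(rho_tot, .Machine$double.xmin)
  nonfluid <- state$mask$role != MF_ROLES[["fluid"]]
  u[nonfluid, ] <- 0
  state$rho <- rho
  state$u <- u
  state
}

# ---- Shan-Chen calibration utilities --------------------------------------

#' Measure the effective pair diffusivity of a Shan-Chen couple
#'
#' Initializes a sinusoidal concentration perturbation about a 50/50 mixture
#' in a periodic box, evolves it, and fits the exponential decay of the mode
#' amplitude: \eqn{A(t) = A_0 e^{-D k^2 t}}. This measures what the coupled
#' two-component system actually diffuses like at the given relaxation time
#' and coupling strength, which is the quantity the mixing use case must
#' calibrate (the coupling reduces the diffusivity below the single-component
#' value \eqn{c_s^2 (\tau - 1/2)}).
#'
#' @param tau relaxation time of both components (lattice units).
#' @param G coupling coefficient.
#' @param rho_tot total density (lattice units).
#' @param nx box length in cells (one wavelength).
#' @param amplitude relative amplitude of the perturbation.
#' @param nsteps evolution steps used for the fit.
#' @return effective diffusivity in lattice units (cells^2 per step).
#' @export
measure_pair_diffusivity <- function(tau, G, rho_tot = 1, nx = 64L,
                                     amplitude = 0.3, nsteps = 400L) {
  lat <- make_lattice("D2Q9")
  mask <- periodic_box_mask(c(nx, 4L))
  st <- new_sim_state(mask, lat, unit_scales(1e-6, 1e-6), ncomp = 2L,
                      periodic = c(TRUE, TRUE), G = G)
  x <- (arrayInd(seq_len(prod(mask$dims)), mask$dims)[, 1] - 0.5) / nx
  k <- 2 * pi / nx
  cA <- 0.5 + amplitude / 2 * sin(2 * pi * x)
  rho <- cbind(rho_tot * cA, rho_tot * (1 - cA))
  st <- initialize_equilibrium(st, rho = rho, tau = tau)
  amp_of <- function(s) {
    s <- refresh_macroscopic(s)
    alpha <- s$rho[, 1] / pmax(rowSums(s$rho), .Machine$double.xmin)
    2 * mean(alpha * sin(2 * pi * x)) / 1  # Fourier coefficient of the mode
  }
  a0 <- amp_of(st)
  st <- lbm_advance(st, nsteps)
  a1 <- amp_of(st)
  if (!(a1 > 0 && a0 > 0)) stop("diffusivity measurement lost the perturbation (unstable or demixing)")
  log(a0 / a1) / (k^2 * nsteps)
}

#' Solve for the relaxation time realizing a target pair diffusivity
#'
#' Inverts \code{\link{measure_pair_diffusivity}} in \code{tau} (the
#' diffusivity is monotone increasing in \code{tau}) by secant iteration on
#' measured values.
#'
#' @param D_target_lat target lattice diffusivity.
#' @param G coupling coefficient.
#' @param rho_tot total density.
#' @param tol relative tolerance on the achieved diffusivity.
#' @return list with \code{tau} and the achieved \code{D_lat}.
#' @export
calibrate_mixing_tau <- function(D_target_lat, G, rho_tot = 1, tol = 5e-3) {
  if (!(D_target_lat > 0)) stop("target diffusivity must be > 0")
  # The coupled pair diffuses like D ~ cs^2 [(tau - 1/2) - tau G 2 rho_A
  # rho_B / rho_tot] (anti-diffusive drift of the velocity-shift forcing), so
  # at a 50/50 mixture D is linear in tau with slope (1 - G rho_tot/2)/3;
  # that closed form seeds a safeguarded secant on measured decays (a failed
  # or negative measurement counts as "tau too low").
  g <- G * rho_tot / 2
  if (g >= 1) stop("coupling too strong for a miscible pair at this density (demixing)")
  slope0 <- (1 - g) / 3
  meas <- function(tau) {
    d <- tryCatch(measure_pair_diffusivity(tau, G, rho_tot, nsteps = 1500L),
                  error = function(e) NA_real_)
    if (!is.na(d) && d <= 0) NA_real_ else d
  }
  t_hi <- max((3 * D_target_lat + 0.5) / (1 - g), 0.505)
  d_hi <- meas(t_hi)
  tries <- 0L
  while ((is.na(d_hi) || d_hi < D_target_lat) && tries < 10L) {
    step <- if (is.na(d_hi)) 0.1 * (t_hi - 0.5) + 0.01 else (D_target_lat - d_hi) / slope0
    t_hi <- t_hi + max(step, 1e-4)
    d_hi <- meas(t_hi)
    tries <- tries + 1L
  }
  if (is.na(d_hi)) stop("diffusivity calibration failed to bracket the target")
  t_lo <- NA_real_; d_lo <- NA_real_
  t2 <- t_hi; d2 <- d_hi
  for (it in 1:15) {
    if (abs(d2 - D_target_lat) <= tol * D_target_lat) break
    if (d2 > D_target_lat) { t_hi <- t2; d_hi <- d2 } else { t_lo <- t2; d_lo <- d2 }
    slope <- if (!is.na(t_lo)) (d_hi - d_lo) / (t_hi - t_lo) else slope0
    if (!is.finite(slope) || slope <= 0) slope <- slope0
    t_next <- t_hi + (D_target_lat - d_hi) / slope
    if (!is.na(t_lo) && (t_next <= t_lo || t_next >= t_hi)) t_next <- (t_lo + t_hi) / 2
    if (is.na(t_lo)) t_next <- max(t_next, 0.5 + 0.5 * (t_hi - 0.5))
    d_next <- meas(t_next)
    if (is.na(d_next)) { t_lo <- t_next; next }
    t2 <- t_next; d2 <- d_next
  }
  list(tau = t2, D_lat = d2)
}

#' Laplace-law calibration of the numerical surface tension
#'
#' Equilibrates static 2D droplets of several radii at coupling \code{G} and
#' fits the interfacial pressure jump against curvature:
#' \eqn{\Delta p = \sigma_{lat}/r} (2D). The pressure includes the
#' Shan-Chen interaction contribution
#' \eqn{p = c_s^2(\rho_A+\rho_B) + c_s^2 G \rho_A \rho_B}.
#'
#' @param G coupling coefficient.
#' @param tau relaxation time for both components.
#' @param radii droplet radii in cells.
#' @param rho_tot total density.
#' @param ambient minority fraction the surrounding phase is initialized at.
#'   Initializing near the coexistence solubility (about 0.09 for the droplet
#'   coupling) avoids a long dissolution transient; the droplet radius is
#'   measured after equilibration in any case.
#' @param nsteps equilibration steps per droplet.
#' @return list with the fitted lattice surface tension \code{sigma_lat},
#'   the fit \code{r_squared}, and the per-droplet table \code{data}.
#' @export
laplace_calibration <- function(G, tau = 1, radii = c(15, 20, 25, 30),
                                rho_tot = 1, ambient = 0.09, nsteps = 8000L) {
  lat <- make_lattice("D2Q9")
  floor <- ambient
  rows <- lapply(radii, function(r) {
    L <- 2L * as.integer(2 * r)
    mask <- periodic_box_mask(c(L, L))
    st <- new_sim_state(mask, lat, unit_scales(1e-6, 1e-6), ncomp = 2L,
                        periodic = c(TRUE, TRUE), G = G)
    xy <- arrayInd(seq_len(prod(mask$dims)), mask$dims)
    rad <- sqrt((xy[, 1] - L / 2 - 0.5)^2 + (xy[, 2] - L / 2 - 0.5)^2)
    inside <- rad <= r
    cA <- ifelse(inside, 0.99, floor)
    st <- initialize_equilibrium(st, rho = cbind(rho_tot * cA, rho_tot * (1 - cA)), tau = tau)
    st <- lbm_advance(st, nsteps)
    st <- refresh_macroscopic(st)
    alpha <- st$rho[, 1] / pmax(rowSums(st$rho), .Machine$double.xmin)
    r_eff <- sqrt(sum(alpha >= 0.5) / pi)    # equilibrated radius, not nominal
    p <- lat$cs2 * (rowSums(st$rho) + G * st$rho[, 1] * st$rho[, 2])
    c(r = r, r_eff = r_eff,
      dp = mean(p[rad <= r_eff / 2]) - mean(p[rad >= min(1.6 * r_eff, L / 2 - 2)]))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  fit <- stats::lm(dp ~ I(1 / r_eff), data = tab)
  list(sigma_lat = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       data = tab)
}
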