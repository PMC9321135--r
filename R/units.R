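#' SI / lattice unit conversion
#'
#' A lattice-Boltzmann run is carried out in nondimensional lattice units in
#' which the cell spacing, the time step and a reference density are all 1.
#' The conversion contract to SI is fixed by the triplet
#' \code{(dx, dt, rho_ref)}: a length \code{L} in metres is \code{L/dx} cells,
#' a velocity \code{u} becomes \code{u*dt/dx}, a kinematic viscosity
#' \code{nu*dt/dx^2}, a pressure \code{p*dt^2/(rho_ref*dx^2)}, and so on.
#'
#' Two guard rails are checked when a driving velocity and viscosity are
#' supplied: the lattice Mach proxy \code{u_lat} must stay below 0.1 (weakly
#' compressible regime) and the BGK relaxation time \code{tau} must lie in
#' \code{(0.5, 3]} for stability and accuracy.
#'
#' @param dx metres per lattice cell.
#' @param dt seconds per lattice step.
#' @param rho_ref kg/m^3 corresponding to lattice density 1.
#' @param u_max optional largest SI speed that will be imposed; checked against
#'   the compressibility guard.
#' @param nu optional SI kinematic viscosity (m^2/s); checked against the
#'   relaxation-time window.
#' @return An object of class \code{"mf_scales"}.
#' @examples
#' sc <- unit_scales(dx = 1e-6, dt = 5e-6, u_max = 0.01)
#' si_to_lattice(0.01, "velocity", sc)  # 0.05
#' @export
unit_scales <- function(dx, dt, rho_ref = 1, u_max = NULL, nu = NULL) {
  stopifnot(dx > 0, dt > 0, rho_ref > 0)
  sc <- structure(list(dx = dx, dt = dt, rho_ref = rho_ref), class = "mf_scales")
  if (!is.null(u_max)) {
    ul <- u_max * dt / dx
    if (ul >= 0.1) {
      stop(sprintf("lattice speed u_lat = %.4g violates the compressibility guard (must be < 0.1); reduce dt", ul))
    }
  }
  if (!is.null(nu)) {
    tau <- tau_from_viscosity(si_to_lattice(nu, "kinematic-viscosity", sc))
    if (!(tau > 0.5 && tau <= 3)) {
      stop(sprintf("relaxation time tau = %.4g outside the stable window (0.5, 3]; adjust dt", tau))
    }
  }
  sc
}

#' @export
print.mf_scales <- function(x, ...) {
  cat(sprintf("Unit scales: dx = %g m, dt = %g s, rho_ref = %g kg/m^3\n", x$dx, x$dt, x$rho_ref))
  invisible(x)
}

# exponents of dx, dt, rho_ref for each supported quantity kind
.mf_unit_exponents <- list(
  `length`              = c(1, 0, 0),
  `time`                = c(0, 1, 0),
  `velocity`            = c(1, -1, 0),
  `density`             = c(0, 0, 1),
  `pressure`            = c(2, -2, 1),
  `kinematic-viscosity` = c(2, -1, 0),
  `surface-tension`     = c(3, -2, 1)
)

#' Convert an SI value to lattice units
#'
#' @param value numeric vector of SI values.
#' @param kind one of \code{"length"}, \code{"time"}, \code{"velocity"},
#'   \code{"density"}, \code{"pressure"}, \code{"kinematic-viscosity"},
#'   \code{"surface-tension"}.
#' @param scales a \code{\link{unit_scales}}.
#' @export
si_to_lattice <- function(value, kind, scales) {
  e <- .mf_unit_exponents[[kind]]
  if (is.null(e)) stop(sprintf("unknown quantity kind '%s'", kind))
  value / (scales$dx^e[1] * scales$dt^e[2] * scales$rho_ref^e[3])
}

#' Convert a lattice value back to SI
#' @inheritParams si_to_lattice
#' @export
lattice_to_si <- function(value, kind, scales) {
  e <- .mf_unit_exponents[[kind]]
  if (is.null(e)) stop(sprintf("unknown quantity kind '%s'", kind))
  value * (scales$dx^e[1] * scales$dt^e[2] * scales$rho_ref^e[3])
}

#' BGK relaxation time from lattice viscosity
#'
#' The kinetic relation \code{nu = cs^2 (tau - 1/2)} with \code{cs^2 = 1/3}
#' (in lattice units, \code{dt = 1}) is the single source of truth tying the
#' relaxation time to the kinematic viscosity.
#'
#' @param nu_lat kinematic viscosity in lattice units.
#' @return relaxation time \code{tau} (lattice units).
#' @export
tau_from_viscosity <- function(nu_lat) {
  if (any(nu_lat <= 0)) stop("lattice viscosity must be > 0")
  3 * nu_lat + 0.5
}

#' Lattice viscosity from a relaxation time
#' @param tau BGK relaxation time (lattice units).
#' @export
viscosity_from_tau <- function(tau) (tau - 0.5) / 3

#' Choose a time step for a channel problem
#'
#' Picks \code{dt} so that the lattice inlet speed equals \code{u_lat} (default
#' 0.05) and then verifies that the relaxation time for the supplied kinematic
#' viscosity lies in the stable window, reducing \code{u_lat} if the viscosity
#' bound binds first.
#'
#' @param dx cell size (m).
#' @param u_in driving speed (m/s).
#' @param nu kinematic viscosity (m^2/s); may be a range (e.g. the
#'   Carreau-Yasuda zero- and infinite-shear values).
#' @param rho_ref reference density (kg/m^3).
#' @param u_lat target lattice speed.
#' @param tau_max upper bound accepted for the relaxation time.
#' @return a \code{\link{unit_scales}} object.
#' @export
auto_scales <- function(dx, u_in, nu, rho_ref = 1, u_lat = 0.05, tau_max = 3) {
  stopifnot(u_in > 0, all(nu > 0))
  dt <- u_lat * dx / u_in
  # largest viscosity limits tau from above
  tmax <- tau_from_viscosity(max(nu) * dt / dx^2)
  if (tmax > tau_max) {
    dt <- (tau_max - 0.5) / 3 * dx^2 / max(nu)
  }
  # smallest viscosity must keep tau > 0.5 (always true for nu > 0)
  unit_scales(dx, dt, rho_ref, u_max = u_in, nu = max(nu))
}
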