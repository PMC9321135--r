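#' Carreau-Yasuda rheology parameters
#'
#' Five-parameter shear-thinning law giving the effective dynamic viscosity as
#' a function of the shear strain rate \code{g} (1/s):
#' \deqn{\mu_{eff}(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'       \left[1+(\lambda\dot\gamma)^a\right]^{(n-1)/a}.}
#'
#' The default parameter values model whole blood.
#'
#' @param mu0 zero-shear viscosity (Pa s).
#' @param mu_inf infinite-shear viscosity (Pa s).
#' @param lam relaxation time (s).
#' @param a,n dimensionless power indices.
#' @return object of class \code{"mf_carreau_yasuda"}.
#' @examples
#' p <- carreau_yasuda()                 # blood
#' carreau_yasuda_viscosity(0, p)        # 22e-3 Pa s
#' carreau_yasuda_viscosity(1e6, p)      # -> 2.2e-3 Pa s
#' @export
carreau_yasuda <- function(mu0 = 22e-3, mu_inf = 2.2e-3, lam = 0.110,
                           a = 0.644, n = 0.392) {
  if (!(mu_inf > 0 && mu0 >= mu_inf)) stop("need mu0 >= mu_inf > 0")
  if (lam < 0) stop("relaxation time lam must be >= 0")
  if (a <= 0) stop("power index a must be > 0")
  structure(list(mu0 = mu0, mu_inf = mu_inf, lam = lam, a = a, n = n),
            class = "mf_carreau_yasuda")
}

#' Effective viscosity of a Carreau-Yasuda fluid
#'
#' @param gamma_dot shear strain rate (1/s), vectorized, must be >= 0.
#' @param p a \code{\link{carreau_yasuda}} object.
#' @return effective dynamic viscosity (Pa s).
#' @export
carreau_yasuda_viscosity <- function(gamma_dot, p) {
  if (any(gamma_dot < 0)) stop("shear rate must be >= 0")
  p$mu_inf + (p$mu0 - p$mu_inf) * (1 + (p$lam * gamma_dot)^p$a)^((p$n - 1) / p$a)
}

#' Fluid specification
#'
#' Bundles the density, the rheology (either a constant Newtonian viscosity or
#' a \code{\link{carreau_yasuda}} parameter set), and the pair-interaction
#' properties used by the two-fluid use cases: the mutual diffusivity
#' \code{D_D} for miscible pairs and the surface-tension coefficient
#' \code{gamma_cd} for immiscible pairs.
#'
#' @param rho density (kg/m^3).
#' @param mu Newtonian dynamic viscosity (Pa s); exclusive with \code{cy}.
#' @param cy a \code{\link{carreau_yasuda}} object; exclusive with \code{mu}.
#' @param D_D pair diffusivity (m^2/s), for miscible pairs.
#' @param gamma_cd surface tension (N/m), for immiscible pairs.
#' @return object of class \code{"mf_fluid"}.
#' @export
fluid_spec <- function(rho, mu = NULL, cy = NULL, D_D = 0, gamma_cd = 0) {
  if (!(rho > 0)) stop("density must be > 0")
  if (is.null(mu) == is.null(cy)) stop("exactly one of 'mu' (Newtonian) or 'cy' (Carreau-Yasuda) must be given")
  if (!is.null(mu) && !(mu > 0)) stop("viscosity must be > 0")
  if (!is.null(cy) && !inherits(cy, "mf_carreau_yasuda")) stop("'cy' must be a carreau_yasuda() object")
  if (D_D < 0) stop("diffusivity must be >= 0")
  if (gamma_cd < 0) stop("surface tension must be >= 0")
  structure(list(rho = rho, mu = mu, cy = cy, D_D = D_D, gamma_cd = gamma_cd),
            class = "mf_fluid")
}

# kinematic viscosity range (m^2/s) of a fluid spec
nu_range <- function(fl) {
  if (!is.null(fl$mu)) rep(fl$mu / fl$rho, 2) else c(fl$cy$mu_inf, fl$cy$mu0) / fl$rho
}

#' Driving conditions for a straight-channel problem
#'
#' Exactly one of the inlet mean velocity \code{u_in} or the applied pressure
#' difference \code{dp} must drive the problem; \code{p_out} is the outlet
#' reference pressure.
#' @param u_in inlet mean velocity (m/s).
#' @param dp applied pressure difference (Pa).
#' @param p_out outlet pressure (Pa).
#' @export
driving_conditions <- function(u_in = NULL, dp = NULL, p_out = 0) {
  if (is.null(u_in) == is.null(dp)) stop("exactly one of 'u_in' or 'dp' must be given")
  vals <- c(u_in, dp, p_out)
  if (!all(is.finite(vals))) stop("driving conditions must be finite")
  structure(list(u_in = u_in, dp = dp, p_out = p_out), class = "mf_driving")
}
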