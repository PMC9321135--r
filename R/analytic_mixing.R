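#' Diffusion distance
#'
#' Characteristic distance travelled by molecules of diffusivity \code{D_D}
#' in time \code{t}: \eqn{d = 2\sqrt{D_D t}}.
#' @param D_D diffusion coefficient (m^2/s), >= 0.
#' @param t time (s), >= 0.
#' @return distance (m).
#' @export
diffusion_distance <- function(D_D, t) {
  if (any(D_D < 0) || any(t < 0)) stop("D_D and t must be >= 0")
  2 * sqrt(D_D * t)
}

#' Cross-channel concentration of two co-flowing streams
#'
#' Series solution of the advection-diffusion balance
#' \eqn{\partial^2 c/\partial y^2 = Pe\, \partial c/\partial x} for two
#' streams entering side by side (concentration 1 on one half of the inlet,
#' 0 on the other):
#' \deqn{c(\tilde x, \eta) = \frac{1}{2} + \frac{2}{\pi} \sum_{n \ge 1}
#'   e^{-\pi^2 (2n-1)^2 \tilde x / Pe}\,
#'   \frac{\sin\!\big(\pi (2n-1)\, \eta\big)}{2n-1},}
#' where \eqn{\eta \in [-1/2, 1/2]} is the cross coordinate with the
#' inlet interface at \eqn{\eta = 0} and the walls at \eqn{\eta = \pm 1/2}
#' (no-flux there, since \eqn{\cos((2n-1)\pi/2) = 0}).
#'
#' The series is summed until the magnitude bound of the next term falls below
#' \code{tail_tol}.
#'
#' @param x_tilde dimensionless axial coordinate (scaling set by the caller).
#' @param eta dimensionless cross coordinate in \code{[-1/2, 1/2]}, vectorized.
#' @param Pe Peclet number (> 0) paired with \code{x_tilde}'s scaling.
#' @param tail_tol truncation tolerance on the next term's magnitude.
#' @param n_max series term budget.
#' @return concentration in \code{[0, 1]} (same length as \code{eta}).
#' @export
mixing_concentration <- function(x_tilde, eta, Pe, tail_tol = 1e-12, n_max = 100000L) {
  if (!(Pe > 0)) stop("Pe must be > 0")
  if (!(tail_tol > 0)) stop("tail_tol must be > 0")
  if (any(abs(eta) > 0.5 + 1e-12)) stop("eta must lie in [-1/2, 1/2]")
  beta <- pi^2 * x_tilde / Pe
  c_out <- rep(0.5, length(eta))
  n <- 1L
  repeat {
    k <- 2 * n - 1
    amp <- (2 / pi) * exp(-beta * k^2) / k
    c_out <- c_out + amp * sin(pi * k * eta)
    nk <- k + 2
    if ((2 / pi) * exp(-beta * nk^2) / nk < tail_tol || n >= n_max) break
    n <- n + 1L
  }
  c_out
}

#' Concentration profile at the measurement line
#'
#' Evaluates \code{\link{mixing_concentration}} at \code{n_points} cell-centre
#' positions across the width at the axial station \code{x_m} of the geometry.
#'
#' Two nondimensionalization conventions are available for forming the
#' \eqn{(\tilde x, Pe)} pair:
#' \describe{
#'   \item{\code{"table"}} (default) all lengths are scaled by the inlet
#'     stream half-width \eqn{b = w/2} and the Peclet number is formed with
#'     the diffusion-distance coefficient \eqn{2 D_D} (the \eqn{d=2\sqrt{D t}}
#'     convention): \eqn{\tilde x = x/b}, \eqn{Pe = u b/(2 D_D)}. This is the
#'     convention calibrated against the published mixing-index tables for
#'     this class of device (see the methods vignette).
#'   \item{\code{"width"}} the textbook scaling with the full channel width:
#'     \eqn{\tilde x = x/w}, \eqn{Pe = u w / D_D}.
#' }
#' Both conventions produce identical inlet steps and far-field limits; they
#' differ only in how fast the transverse modes decay with \eqn{x}.
#'
#' @param geom a \code{\link{channel_geometry}} (width \code{w}, line
#'   \code{x_m}).
#' @param u_in mean axial velocity (m/s).
#' @param D_D pair diffusivity (m^2/s), > 0.
#' @param n_points number of cell-centre samples across the width (defaults
#'   to the number of 1-um cells).
#' @param convention \code{"table"} or \code{"width"}.
#' @param tail_tol series truncation tolerance.
#' @return An object of class \code{"mf_conc_profile"}: data frame with the
#'   dimensionless cross positions \code{y} (0..1), positions \code{z} (m)
#'   and concentrations \code{alpha}; the station is kept in attribute
#'   \code{x}.
#' @export
mixing_profile_at_line <- function(geom, u_in, D_D,
                                   n_points = max(2L, round(geom$w / 1e-6)),
                                   convention = c("table", "width"),
                                   tail_tol = 1e-12) {
  stopifnot(inherits(geom, "mf_channel"))
  convention <- match.arg(convention)
  if (!(D_D > 0)) stop("D_D must be > 0")
  if (!(u_in > 0)) stop("u_in must be > 0")
  w <- geom$w; x <- geom$x_m
  sc <- switch(convention,
    table = list(x_tilde = x / (w / 2), Pe = u_in * (w / 2) / (2 * D_D)),
    width = list(x_tilde = x / w,       Pe = u_in * w / D_D))
  y <- (seq_len(n_points) - 0.5) / n_points
  alpha <- mixing_concentration(sc$x_tilde, y - 0.5, sc$Pe, tail_tol = tail_tol)
  structure(data.frame(y = y, z = y * w, alpha = alpha),
            class = c("mf_conc_profile", "data.frame"),
            x = x, convention = convention, Pe = sc$Pe)
}

#' Effective axial decay parameter of a mixing convention
#'
#' Returns the modal decay coefficient \eqn{\beta} such that the k-th odd
#' transverse mode decays like \eqn{\exp(-\beta k^2)} at station \code{x}:
#' \eqn{\beta = \pi^2 \tilde x / Pe}. Used to translate the 1D convention into
#' the effective physical diffusivity that a field simulation must realize to
#' be comparable, \eqn{D_{eff} = \beta u w^2 / (\pi^2 x)}.
#' @inheritParams mixing_profile_at_line
#' @param x axial station (m).
#' @param w channel width (m).
#' @export
mixing_decay_beta <- function(x, w, u_in, D_D, convention = c("table", "width")) {
  convention <- match.arg(convention)
  switch(convention,
         table = pi^2 * (x / (w / 2)) / (u_in * (w / 2) / (2 * D_D)),
         width = pi^2 * (x / w) / (u_in * w / D_D))
}

#' Effective diffusivity implied by a mixing convention
#'
#' The physical diffusivity that reproduces the convention's modal decay under
#' the dimensionally consistent scaling; equals \code{D_D} for the
#' \code{"width"} convention and \code{8 * D_D} for the \code{"table"} one.
#' @inheritParams mixing_decay_beta
#' @export
mixing_effective_diffusivity <- function(u_in, w, x, D_D, convention = c("table", "width")) {
  beta <- mixing_decay_beta(x, w, u_in, D_D, convention)
  beta * u_in * w^2 / (pi^2 * x)
}
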