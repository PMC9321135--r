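#' Laplace pressure across a droplet interface
#'
#' Interfacial pressure jump between carrier and droplet,
#' \eqn{p_c - p_d = 2\gamma_{cd}/r}.
#' @param gamma_cd surface tension coefficient (N/m).
#' @param r droplet radius (m), > 0.
#' @return pressure jump (Pa).
#' @export
laplace_pressure <- function(gamma_cd, r) {
  if (any(r <= 0)) stop("radius must be > 0")
  if (any(gamma_cd < 0)) stop("surface tension must be >= 0")
  2 * gamma_cd / r
}

#' Bifurcation network for a given abstraction level
#'
#' Builds the three-edge hydraulic network of the bifurcation (inlet segment to
#' junction centre, two branch segments to the outlets) with resistances per
#' the rectangular-duct series (3D) or the parallel-plate law per unit depth
#' (2D), a fixed inlet flow matching \code{u_in}, and the two outlet
#' pressures.
#'
#' @param geom a \code{\link{bifurcation_geometry}}.
#' @param mu carrier dynamic viscosity (Pa s).
#' @param u_in inlet mean velocity (m/s).
#' @param level \code{"2d"} or \code{"3d"}.
#' @return list: the solved network (\code{pressures}, \code{flows}), the
#'   cross-section area \code{A}, and the branch flows \code{Q_top},
#'   \code{Q_bot}, \code{Q_in}.
#' @export
bifurcation_network <- function(geom, mu, u_in, level = c("3d", "2d")) {
  level <- match.arg(level)
  w <- geom$w
  len_in <- geom$l + w / 2
  len_br <- branch_extent(geom) + w / 2
  if (level == "3d") {
    if (is.null(geom$h)) stop("3D network needs the geometry height 'h'")
    A <- w * geom$h
    Rin <- hydraulic_resistance(channel_geometry(len_in, w, geom$h), mu)
    Rbr <- hydraulic_resistance(channel_geometry(len_br, w, geom$h), mu)
  } else {
    A <- w  # per unit depth
    Rin <- plane_resistance(len_in, w, mu)
    Rbr <- plane_resistance(len_br, w, mu)
  }
  net <- hydraulic_network(
    edges = data.frame(from = c("inlet", "junction", "junction"),
                       to = c("junction", "top", "bottom"),
                       R = c(Rin, Rbr, Rbr)),
    fixed_p = c(top = geom$p_top, bottom = geom$p_bot),
    fixed_q = c(inlet = u_in * A))
  sol <- solve_network(net)
  Q <- sol$flows$Q
  list(solution = sol, A = A,
       Q_in = Q[1], Q_top = Q[2], Q_bot = Q[3])
}

#' 1D droplet trajectory through a bifurcation
#'
#' Advances the droplet's trailing edge along the centre path at the slip
#' velocity \eqn{u_d = \alpha Q / A} of the segment currently containing it
#' (inlet flow up to the junction centre, then the chosen branch flow). The
#' branch is the one carrying the larger flow; ties go to \code{tie_break}.
#' The droplet body is mapped a length \code{dl} ahead of the trailing edge
#' along the path, undeformed.
#'
#' @param geom a \code{\link{bifurcation_geometry}}.
#' @param net a solved \code{\link{bifurcation_network}} result.
#' @param alpha slip factor (droplet speed over mean carrier speed), > 0.
#' @param dl droplet length (m), >= 0.
#' @param t_samples times (s) at which to sample the trailing-edge position;
#'   defaults to 101 samples up to the outlet arrival time.
#' @param s0 initial trailing-edge path position (m).
#' @param tie_break branch taken at exactly equal flows.
#' @return An object of class \code{"mf_trajectory"}: data frame \code{t},
#'   \code{s} (trailing edge path coordinate, m) with attributes
#'   \code{branch}, \code{dl}, \code{t_arrive} (trailing edge at path end) and
#'   the segment table.
#' @export
droplet_trajectory <- function(geom, net, alpha, dl, t_samples = NULL, s0 = 0,
                               tie_break = c("top", "bottom")) {
  tie_break <- match.arg(tie_break)
  if (!(alpha > 0)) stop("slip factor must be > 0")
  if (dl < 0) stop("droplet length must be >= 0")
  w <- geom$w
  s_junction <- geom$l + w / 2
  s_end <- s_junction + w / 2 + branch_extent(geom)
  branch <- if (net$Q_top > net$Q_bot) "top"
            else if (net$Q_bot > net$Q_top) "bottom"
            else tie_break
  Q_br <- if (branch == "top") net$Q_top else net$Q_bot
  u1 <- alpha * net$Q_in / net$A
  u2 <- alpha * Q_br / net$A
  if (u1 <= 0 || u2 <= 0) stop("path flow must be positive for a forward trajectory")
  if (s0 + dl > s_end) stop("droplet does not fit on the remaining path")
  seg <- data.frame(s_from = c(s0, s_junction), s_to = c(s_junction, s_end),
                    u_d = c(u1, u2))
  t_junction <- (s_junction - s0) / u1
  t_arrive <- t_junction + (s_end - s_junction) / u2
  if (is.null(t_samples)) t_samples <- seq(0, t_arrive, length.out = 101L)
  if (any(t_samples < 0)) stop("sample times must be >= 0")
  s <- ifelse(t_samples <= t_junction,
              s0 + u1 * t_samples,
              pmin(s_junction + u2 * (t_samples - t_junction), s_end))
  structure(data.frame(t = t_samples, s = s),
            class = c("mf_trajectory", "data.frame"),
            branch = branch, dl = dl, segments = seg,
            t_junction = t_junction, t_arrive = t_arrive, s_end = s_end)
}

#' @export
print.mf_trajectory <- function(x, ...) {
  cat(sprintf("Droplet trajectory: branch '%s', trailing edge reaches path end (s = %g um) at t = %g ms\n",
              attr(x, "branch"), attr(x, "s_end") * 1e6, attr(x, "t_arrive") * 1e3))
  invisible(x)
}

#' Time at which the 1D trailing edge reaches a path position
#' @param traj an \code{"mf_trajectory"}.
#' @param s path coordinate (m).
#' @export
trajectory_time_at <- function(traj, s) {
  seg <- attr(traj, "segments")
  tj <- attr(traj, "t_junction")
  if (s <= seg$s_from[1]) return(0)
  if (s <= seg$s_to[1]) return((s - seg$s_from[1]) / seg$u_d[1])
  tj + (pmin(s, seg$s_to[2]) - seg$s_from[2]) / seg$u_d[2]
}
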