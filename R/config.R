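# Declarative configuration: JSON or YAML, SI quantities with explicit unit
# suffixes in key names (e.g. width_um, u_in_mm_s, density_kg_m3).

# recognized suffixes and their factor to SI
.mf_suffixes <- c(
  m = 1, um = 1e-6, mm = 1e-3, nm = 1e-9,
  s = 1, ms = 1e-3, us = 1e-6,
  m_s = 1, mm_s = 1e-3, um_s = 1e-6,
  pa = 1, pa_s = 1, pas = 1,
  m2_s = 1, mm2_s = 1e-6, um2_s = 1e-12,
  n_m = 1, mn_m = 1e-3,
  kg_m3 = 1, g_m3 = 1e-3)

# fetch `base` or `base_<suffix>` from a config block; NULL if absent
cfg_get <- function(block, base, where, required = TRUE, default = NULL) {
  nms <- names(block)
  if (is.null(nms)) nms <- character(0)
  hit <- nms[nms == base | startsWith(nms, paste0(base, "_"))]
  if (length(hit) == 0L) {
    if (required && is.null(default)) {
      stop(sprintf("config error at '%s': missing field '%s'", where, base))
    }
    return(default)
  }
  if (length(hit) > 1L) stop(sprintf("config error at '%s': field '%s' given more than once", where, base))
  val <- block[[hit]]
  if (!is.numeric(val)) stop(sprintf("config error at '%s.%s': not numeric", where, hit))
  suf <- sub(paste0("^", base, "_?"), "", hit)
  if (suf == "") return(val)
  fac <- .mf_suffixes[[tolower(suf)]]
  if (is.null(fac)) stop(sprintf("config error at '%s.%s': unknown unit suffix '%s'", where, hit, suf))
  val * fac
}

#' Load and validate a use-case configuration
#'
#' Reads a JSON or YAML configuration describing one of the three use cases
#' (\code{"flow"}, \code{"mix"}, \code{"droplet"}), converts unit-suffixed
#' keys to SI, fills defaults, and enforces the type invariants (positive
#' geometry, exactly one rheology, the lattice compressibility guard and the
#' relaxation-time window).
#'
#' @param path file ending in \code{.json}, \code{.yaml} or \code{.yml}.
#' @return object of class \code{"mf_config"}.
#' @examples
#' cfg <- load_config(system.file("extdata", "flow_blood.json", package = "mfsim"))
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  case <- raw$case
  if (is.null(case) || !case %in% c("flow", "mix", "droplet")) {
    stop("config error at 'case': must be one of 'flow', 'mix', 'droplet'")
  }
  g <- raw$geometry
  if (is.null(g)) stop("config error: missing 'geometry' block")
  sv <- if (is.null(raw$solver)) list() else raw$solver
  dx <- cfg_get(sv, "dx", "solver", default = 1e-6)
  u_lat <- if (!is.null(sv$u_lat)) sv$u_lat else 0.05
  tol <- if (!is.null(sv$tolerance)) sv$tolerance else 1e-5
  window <- if (!is.null(sv$window)) as.integer(sv$window) else 1000L
  max_steps <- if (!is.null(sv$max_steps)) as.integer(sv$max_steps) else 200000L

  fl_block <- raw$fluid
  if (is.null(fl_block)) stop("config error: missing 'fluid' block")
  rho <- cfg_get(fl_block, "density", "fluid")
  cy <- NULL; mu <- NULL
  if (!is.null(fl_block$carreau_yasuda)) {
    cyb <- fl_block$carreau_yasuda
    cy <- carreau_yasuda(
      mu0 = cfg_get(cyb, "mu0", "fluid.carreau_yasuda"),
      mu_inf = cfg_get(cyb, "mu_inf", "fluid.carreau_yasuda"),
      lam = cfg_get(cyb, "lambda", "fluid.carreau_yasuda"),
      a = cyb$a, n = cyb$n)
  } else if (!is.null(fl_block$viscosity) || any(startsWith(names(fl_block), "viscosity"))) {
    mu <- cfg_get(fl_block, "viscosity", "fluid")
  } else if (any(startsWith(names(fl_block), "kinematic_viscosity"))) {
    mu <- cfg_get(fl_block, "kinematic_viscosity", "fluid") * rho
  } else stop("config error at 'fluid': need 'viscosity', 'kinematic_viscosity' or a 'carreau_yasuda' block")
  fluid <- fluid_spec(rho, mu = mu, cy = cy,
                      D_D = cfg_get(fl_block, "diffusivity", "fluid", required = FALSE, default = 0),
                      gamma_cd = cfg_get(fl_block, "surface_tension", "fluid", required = FALSE, default = 0))

  dr <- raw$driving
  if (is.null(dr)) stop("config error: missing 'driving' block")
  u_in <- cfg_get(dr, "u_in", "driving", required = FALSE)
  dp <- cfg_get(dr, "dp", "driving", required = FALSE)
  p_out <- cfg_get(dr, "p_out", "driving", required = FALSE, default = 0)
  driving <- driving_conditions(u_in = u_in, dp = dp, p_out = p_out)

  if (case == "droplet") {
    geom <- bifurcation_geometry(
      l = cfg_get(g, "length", "geometry"),
      k = cfg_get(g, "branch_length", "geometry"),
      w = cfg_get(g, "width", "geometry"),
      h = cfg_get(g, "height", "geometry", required = FALSE),
      p_top = cfg_get(g, "p_top", "geometry", required = FALSE, default = 0),
      p_bot = cfg_get(g, "p_bot", "geometry", required = FALSE, default = 0),
      branch_measure = if (is.null(g$branch_measure)) "edge" else g$branch_measure)
  } else {
    geom <- channel_geometry(
      l = cfg_get(g, "length", "geometry"),
      w = cfg_get(g, "width", "geometry"),
      h = cfg_get(g, "height", "geometry", required = FALSE),
      x_m = cfg_get(g, "measurement_line", "geometry",
                    required = FALSE, default = 0.8 * cfg_get(g, "length", "geometry")))
  }

  sc_block <- raw$shan_chen
  G <- if (!is.null(sc_block)) sc_block$G else 0
  minority_floor <- if (!is.null(sc_block$minority_floor)) sc_block$minority_floor else 0.01
  sc_rho0 <- if (!is.null(sc_block$rho0)) sc_block$rho0 else 2
  if (!is.null(sc_block)) {
    if (G < 0) stop("config error at 'shan_chen.G': must be >= 0")
    if (!(minority_floor > 0 && minority_floor <= 0.1)) {
      stop("config error at 'shan_chen.minority_floor': must lie in (0, 0.1]")
    }
  }

  droplet <- NULL
  if (case == "droplet") {
    db <- raw$droplet
    if (is.null(db)) stop("config error: missing 'droplet' block")
    droplet <- list(
      dl = cfg_get(db, "length", "droplet"),
      alpha = if (is.null(db$slip_factor)) stop("config error at 'droplet': missing field 'slip_factor'") else db$slip_factor,
      gap_cells = if (is.null(db$gap_cells)) 1L else as.integer(db$gap_cells),
      s0 = cfg_get(db, "start", "droplet", required = FALSE, default = 50e-6))
  }

  # lattice-unit guards: constructing the scales enforces the compressibility
  # guard and (for a Newtonian fluid) the relaxation-time window
  if (!is.null(u_in)) {
    if (u_lat >= 0.1) stop("config error at 'solver.u_lat': compressibility guard requires u_lat < 0.1")
    dt <- u_lat * dx / u_in
    unit_scales(dx, dt, rho_ref = fluid$rho, u_max = u_in)
  }

  mixing_convention <- if (!is.null(raw$mixing) && !is.null(raw$mixing$convention)) {
    raw$mixing$convention
  } else "table"
  # NULL means: calibrate the pair's reference density at run time so the
  # measured coupled diffusivity matches the target
  mixing_rho0 <- if (!is.null(raw$mixing) && !is.null(raw$mixing$rho0)) raw$mixing$rho0 else NULL

  structure(list(case = case, geometry = geom, fluid = fluid, driving = driving,
                 solver = list(dx = dx, u_lat = u_lat, tolerance = tol,
                               window = window, max_steps = max_steps),
                 G = G, minority_floor = minority_floor, sc_rho0 = sc_rho0,
                 droplet = droplet, mixing_convention = mixing_convention,
                 mixing_rho0 = mixing_rho0,
                 echo = raw),
            class = "mf_config")
}

#' @export
print.mf_config <- function(x, ...) {
  cat(sprintf("mfsim config: case '%s'\n", x$case))
  print(x$geometry)
  invisible(x)
}

#' Path of a shipped use-case configuration
#' @param name one of \code{"flow_blood"}, \code{"mix_straight"},
#'   \code{"droplet_bifurcation"}.
#' @export
example_config <- function(name = c("flow_blood", "mix_straight", "droplet_bifurcation")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".json"), package = "mfsim", mustWork = TRUE)
}
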