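#' Rectangular channel geometry
#'
#' Describes a straight rectangular microchannel. All dimensions are in SI
#' units (metres). For 2D problems the height is omitted and the channel is
#' treated as a pair of parallel plates separated by the width \code{w}.
#'
#' @param l channel length (m).
#' @param w channel width (m); the coordinate across which profiles are taken.
#' @param h channel height (m), or \code{NULL} for a 2D (parallel-plate) domain.
#' @param x_m position of the measurement line, as a distance downstream of the
#'   inlet (m). Profiles are extracted on the cell-centre column nearest this
#'   station. Defaults to \code{0.8 * l}.
#' @return An object of class \code{"mf_channel"}.
#' @examples
#' channel_geometry(l = 500e-6, w = 100e-6, x_m = 400e-6)
#' @export
channel_geometry <- function(l, w, h = NULL, x_m = 0.8 * l) {
  stopifnot(is.numeric(l), is.numeric(w), length(l) == 1L, length(w) == 1L)
  if (!(l > 0)) stop("channel length 'l' must be > 0")
  if (!(w > 0)) stop("channel width 'w' must be > 0")
  if (!is.null(h)) {
    if (!(is.numeric(h) && length(h) == 1L && h > 0)) stop("channel height 'h' must be > 0 when given")
  }
  if (!(x_m > 0 && x_m <= l)) stop("measurement line 'x_m' must satisfy 0 < x_m <= l")
  structure(list(l = l, w = w, h = h, x_m = x_m), class = "mf_channel")
}

#' Bifurcation (T-junction) geometry
#'
#' A straight inlet channel of length \code{l} that ends in a square junction
#' from which two branches of length \code{k} extend perpendicularly, one up
#' and one down. Each branch ends in its own pressure outlet. The droplet is
#' steered by the difference between the two outlet pressures; the branch with
#' the lower outlet pressure carries the larger flow.
#'
#' The extent of the branch channels beyond the junction is ambiguous when only
#' \code{k} is quoted: \code{branch_measure = "edge"} (default) places the
#' outlet a distance \code{k} beyond the junction edge, while \code{"center"}
#' measures \code{k} from the junction centre (branch extent \code{k - w/2}
#' beyond the edge).
#'
#' @param l inlet channel length (m).
#' @param k branch length (m).
#' @param w channel width (m), shared by inlet and branches.
#' @param h channel height (m), or \code{NULL} for 2D.
#' @param p_top,p_bot outlet pressures (Pa) of the top and bottom branch.
#' @param branch_measure \code{"edge"} or \code{"center"}, see Details.
#' @return An object of class \code{"mf_bifurcation"}.
#' @export
bifurcation_geometry <- function(l, k, w, h = NULL, p_top = 0, p_bot = 0,
                                 branch_measure = c("edge", "center")) {
  branch_measure <- match.arg(branch_measure)
  for (nm in c("l", "k", "w")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && v > 0)) stop(sprintf("'%s' must be a positive number", nm))
  }
  if (!is.null(h) && !(is.numeric(h) && length(h) == 1L && h > 0)) stop("'h' must be > 0 when given")
  if (!all(is.finite(c(p_top, p_bot)))) stop("outlet pressures must be finite")
  if (branch_measure == "center" && k <= w / 2) {
    stop("with branch_measure = 'center' the branch length k must exceed w/2")
  }
  structure(list(l = l, k = k, w = w, h = h, p_top = p_top, p_bot = p_bot,
                 branch_measure = branch_measure),
            class = "mf_bifurcation")
}

#' @export
print.mf_channel <- function(x, ...) {
  cat(sprintf("Rectangular channel: l = %g um, w = %g um%s, line m at %g um\n",
              x$l * 1e6, x$w * 1e6,
              if (is.null(x$h)) " (2D)" else sprintf(", h = %g um", x$h * 1e6),
              x$x_m * 1e6))
  invisible(x)
}

#' @export
print.mf_bifurcation <- function(x, ...) {
  cat(sprintf("Bifurcation: l = %g um, k = %g um (%s), w = %g um%s, p_top = %g Pa, p_bot = %g Pa\n",
              x$l * 1e6, x$k * 1e6, x$branch_measure, x$w * 1e6,
              if (is.null(x$h)) " (2D)" else sprintf(", h = %g um", x$h * 1e6),
              x$p_top, x$p_bot))
  invisible(x)
}

# Branch channel extent beyond the junction square edge, in metres.
branch_extent <- function(geom) {
  if (geom$branch_measure == "edge") geom$k else geom$k - geom$w / 2
}

# ---- cell-role masks -------------------------------------------------------

#' Cell roles used in mask grids
#'
#' Integer codes labelling every cell of a rasterized domain:
#' \code{0} fluid, \code{1} wall, \code{2} inlet, \code{3} primary (top)
#' pressure outlet, \code{4} secondary (bottom) outlet. Exported as a named
#' vector for readability.
#' @export
MF_ROLES <- c(fluid = 0L, wall = 1L, inlet = 2L, outlet = 3L, outlet2 = 4L)

# number of cells spanned by a physical extent; errors if not representable
# (an integer multiple of dx up to floating-point slack)
cells_of <- function(extent, dx, axis) {
  n <- extent / dx
  if (abs(n - round(n)) > 1e-6 * max(1, n)) {
    stop(sprintf("extent along '%s' (%g m) is not an integer multiple of dx = %g m", axis, extent, dx))
  }
  as.integer(round(n))
}

new_mask <- function(role, dims, dx, origin = rep(0, length(dims))) {
  structure(list(role = role, dims = dims, dx = dx, origin = origin),
            class = "mf_mask")
}

#' @export
print.mf_mask <- function(x, ...) {
  tab <- tabulate(x$role + 1L, nbins = 5L)
  cat(sprintf("Cell-role mask %s at dx = %g um: %d fluid, %d wall, %d inlet, %d outlet, %d outlet2\n",
              paste(x$dims, collapse = " x "), x$dx * 1e6,
              tab[1], tab[2], tab[3], tab[4], tab[5]))
  invisible(x)
}

# linear index helpers (1-based, x fastest)
mask_index <- function(dims, ix, iy, iz = NULL) {
  if (length(dims) == 2L) ix + dims[1] * (iy - 1L)
  else ix + dims[1] * ((iy - 1L) + dims[2] * (iz - 1L))
}

#' Rasterize a straight channel into a cell-role mask
#'
#' The fluid region spans exactly \code{l/dx} by \code{w/dx} (by \code{h/dx})
#' cells; walls are one cell thick outside the fluid so that the halfway
#' bounce-back plane of the solver coincides with the physical wall. The inlet
#' occupies the full left face and the outlet the full right face.
#'
#' @param geom a \code{\link{channel_geometry}}.
#' @param scales a \code{\link{unit_scales}} object (only \code{dx} is used).
#' @param dims 2 or 3.
#' @return An object of class \code{"mf_mask"}: integer role vector plus grid
#'   metadata (\code{dims}, \code{dx}).
#' @export
build_channel_mask <- function(geom, scales, dims = if (is.null(geom$h)) 2L else 3L) {
  stopifnot(inherits(geom, "mf_channel"))
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (dims == 3L && is.null(geom$h)) stop("3D mask requested but geometry has no height 'h'")
  dx <- scales$dx
  nx <- cells_of(geom$l, dx, "l"); ny <- cells_of(geom$w, dx, "w")
  if (dims == 2L) {
    gd <- c(nx + 2L, ny + 2L)
    role <- rep(MF_ROLES[["wall"]], prod(gd))
    ix <- rep(seq_len(nx) + 1L, times = ny)
    iy <- rep(seq_len(ny) + 1L, each = nx)
    role[mask_index(gd, ix, iy)] <- MF_ROLES[["fluid"]]
    role[mask_index(gd, rep(1L, ny), seq_len(ny) + 1L)] <- MF_ROLES[["inlet"]]
    role[mask_index(gd, rep(nx + 2L, ny), seq_len(ny) + 1L)] <- MF_ROLES[["outlet"]]
  } else {
    nz <- cells_of(geom$h, dx, "h")
    gd <- c(nx + 2L, ny + 2L, nz + 2L)
    role <- rep(MF_ROLES[["wall"]], prod(gd))
    idx <- expand.grid(ix = seq_len(nx) + 1L, iy = seq_len(ny) + 1L, iz = seq_len(nz) + 1L)
    role[mask_index(gd, idx$ix, idx$iy, idx$iz)] <- MF_ROLES[["fluid"]]
    face <- expand.grid(iy = seq_len(ny) + 1L, iz = seq_len(nz) + 1L)
    role[mask_index(gd, rep(1L, nrow(face)), face$iy, face$iz)] <- MF_ROLES[["inlet"]]
    role[mask_index(gd, rep(nx + 2L, nrow(face)), face$iy, face$iz)] <- MF_ROLES[["outlet"]]
  }
  new_mask(role, gd, dx)
}

#' Rasterize a bifurcation into a cell-role mask
#'
#' Inlet channel along +x, junction square at its end, branches along +y and
#' -y ending in the two pressure outlets (role codes 3 = top, 4 = bottom).
#'
#' @inheritParams build_channel_mask
#' @param geom a \code{\link{bifurcation_geometry}}.
#' @return An \code{"mf_mask"}; the attribute \code{junction} holds the cell
#'   index ranges of the inlet channel, junction square and branches, used by
#'   the droplet-tracking path coordinate.
#' @export
build_bifurcation_mask <- function(geom, scales, dims = if (is.null(geom$h)) 2L else 3L) {
  stopifnot(inherits(geom, "mf_bifurcation"))
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (dims == 3L && is.null(geom$h)) stop("3D mask requested but geometry has no height 'h'")
  dx <- scales$dx
  nl <- cells_of(geom$l, dx, "l")
  nw <- cells_of(geom$w, dx, "w")
  nb <- cells_of(branch_extent(geom), dx, "k")
  if (nb < 1L) stop("branch extent must be at least one cell ('k' too small)")
  nx <- nl + nw          # fluid extent along x: inlet channel + junction square
  ny <- nw + 2L * nb     # fluid extent along y: two branches + junction width
  ylo <- nb + 1L         # first y cell (1-based, within fluid frame) of the inlet channel
  yhi <- nb + nw
  build_plane <- function() {
    gd <- c(nx + 2L, ny + 2L)
    role <- rep(MF_ROLES[["wall"]], prod(gd))
    # inlet channel + junction square
    idx <- expand.grid(ix = seq_len(nx) + 1L, iy = (ylo:yhi) + 1L)
    role[mask_index(gd, idx$ix, idx$iy)] <- MF_ROLES[["fluid"]]
    # branches (over the junction's x range)
    bx <- (nl + 1L):nx
    top <- expand.grid(ix = bx + 1L, iy = ((yhi + 1L):(yhi + nb)) + 1L)
    bot <- expand.grid(ix = bx + 1L, iy = (1L:nb) + 1L)
    role[mask_index(gd, top$ix, top$iy)] <- MF_ROLES[["fluid"]]
    role[mask_index(gd, bot$ix, bot$iy)] <- MF_ROLES[["fluid"]]
    # inlet face: full left face of the inlet channel
    role[mask_index(gd, rep(1L, nw), (ylo:yhi) + 1L)] <- MF_ROLES[["inlet"]]
    # outlets: ends of the branches
    role[mask_index(gd, bx + 1L, rep(yhi + nb + 2L, nw))] <- MF_ROLES[["outlet"]]
    role[mask_index(gd, bx + 1L, rep(1L, nw))] <- MF_ROLES[["outlet2"]]
    list(role = role, gd = gd)
  }
  pl <- build_plane()
  if (dims == 2L) {
    m <- new_mask(pl$role, pl$gd, dx)
  } else {
    nz <- cells_of(geom$h, dx, "h")
    gd <- c(pl$gd, nz + 2L)
    role <- rep(MF_ROLES[["wall"]], prod(gd))
    for (iz in seq_len(nz) + 1L) {
      role[(iz - 1L) * prod(pl$gd) + seq_len(prod(pl$gd))] <- pl$role
    }
    m <- new_mask(role, gd, dx)
  }
  attr(m, "junction") <- list(nl = nl, nw = nw, nb = nb, ylo = ylo, yhi = yhi)
  m
}

#' Flood-fill connectivity of the fluid region
#'
#' Returns \code{TRUE} if every fluid cell of the mask is reachable from the
#' inlet face by face-adjacency (through fluid cells).
#' @param mask an \code{"mf_mask"}.
#' @export
mask_connected <- function(mask) {
  role <- mask$role; gd <- mask$dims
  d <- length(gd)
  open <- role == MF_ROLES[["fluid"]]
  seed <- which(role == MF_ROLES[["inlet"]])
  # neighbour offsets along each axis
  strides <- c(1L, gd[1], if (d == 3L) gd[1] * gd[2])
  visited <- logical(length(role))
  frontier <- unique(unlist(lapply(seq_len(d), function(a) c(seed + strides[a], seed - strides[a]))))
  frontier <- frontier[frontier >= 1L & frontier <= length(role)]
  frontier <- frontier[open[frontier]]
  visited[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- integer(0)
    for (a in seq_len(d)) {
      for (s in c(strides[a], -strides[a])) {
        cand <- frontier + s
        cand <- cand[cand >= 1L & cand <= length(role)]
        cand <- cand[open[cand] & !visited[cand]]
        visited[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
    }
    frontier <- unique(nxt)
  }
  all(visited[open])
}
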