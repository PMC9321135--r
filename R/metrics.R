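#' Absolute Mixing Index
#'
#' Normalized deviation of a concentration profile from its cross-sectional
#' mean:
#' \deqn{AMI = \frac{1}{N} \sum_{i=1}^N \frac{|\alpha_i - \langle\alpha\rangle|}
#'   {\langle\alpha\rangle},}
#' which is 0 for a fully mixed (uniform) profile and 1 for the unmixed
#' half-and-half step. A root-mean-square variant
#' (\eqn{\sqrt{\langle(\alpha-\langle\alpha\rangle)^2\rangle}/\langle\alpha\rangle})
#' is available behind \code{variant = "rms"}; it shares the same endpoints
#' but weights large deviations more.
#'
#' @param alpha concentration samples in \code{[0, 1]}, or an
#'   \code{"mf_conc_profile"}.
#' @param variant \code{"mad"} (default) or \code{"rms"}.
#' @return the mixing index (>= 0).
#' @examples
#' absolute_mixing_index(c(1, 0.5, 0))  # 2/3
#' @export
absolute_mixing_index <- function(alpha, variant = c("mad", "rms")) {
  variant <- match.arg(variant)
  if (inherits(alpha, "mf_conc_profile")) alpha <- alpha$alpha
  if (length(alpha) < 2L) stop("need at least two samples")
  m <- mean(alpha)
  if (!(m > 0)) stop("profile mean is zero; AMI undefined")
  if (variant == "mad") mean(abs(alpha - m)) / m else sqrt(mean((alpha - m)^2)) / m
}

#' Extract a cross-channel profile from a field
#'
#' Samples a cell field along the cross-section at the station nearest
#' \code{x_m} (cell-centre convention). For 2D masks this is the column of
#' width cells; for 3D the full cross-section plane.
#'
#' @param field numeric vector over the mask's cells (e.g. a velocity
#'   component or a concentration).
#' @param mask the \code{"mf_mask"} the field lives on.
#' @param x_m measurement station (m downstream of the inlet face).
#' @return data frame with cross positions \code{z} (m from the near wall;
#'   plus \code{z2} for 3D) and \code{value}, ordered by position.
#' @export
extract_profile <- function(field, mask, x_m) {
  gd <- mask$dims; dx <- mask$dx
  # fluid columns start at ix = 2 (one boundary layer); cell centres at
  # (ix - 1.5) * dx downstream of the inlet face
  ix <- round(x_m / dx + 1.5)
  if (ix < 2 || ix > gd[1] - 1) stop("measurement line lies outside the domain")
  idx <- seq_len(prod(gd))
  co <- arrayInd(idx, gd)
  sel <- co[, 1] == ix & mask$role == MF_ROLES[["fluid"]]
  if (!any(sel)) stop("measurement line crosses no fluid cells")
  if (length(gd) == 2L) {
    ord <- order(co[sel, 2])
    out <- data.frame(z = (co[sel, 2][ord] - 1.5) * dx, value = field[sel][ord])
  } else {
    ord <- order(co[sel, 3], co[sel, 2])
    out <- data.frame(z = (co[sel, 2][ord] - 1.5) * dx,
                      z2 = (co[sel, 3][ord] - 1.5) * dx,
                      value = field[sel][ord])
  }
  out
}

# path coordinate of every cell of a bifurcation mask (m); NA off-path cells
bifurcation_path_coordinate <- function(mask) {
  j <- attr(mask, "junction")
  if (is.null(j)) stop("mask has no junction metadata (not a bifurcation mask?)")
  gd <- mask$dims; dx <- mask$dx
  co <- arrayInd(seq_len(prod(gd)), gd)
  x <- (co[, 1] - 1.5) * dx                      # downstream of inlet face
  # y measured from the inlet channel centreline
  yc <- (j$ylo + j$yhi) / 2 + 1                  # centre row (grid frame)
  y <- (co[, 2] - yc) * dx
  half_w <- j$nw / 2 * dx
  s_corner <- (j$nl + j$nw / 2) * dx             # junction centre
  s <- ifelse(abs(y) <= half_w + 1e-12, x, s_corner + abs(y))
  s
}

#' Label connected components of a cell set
#'
#' Face-adjacency flood fill over the mask grid.
#' @param cells logical vector over the mask's cells.
#' @param dims grid dimensions.
#' @return integer vector of component labels (0 outside the set).
#' @export
label_components <- function(cells, dims) {
  lab <- integer(length(cells))
  strides <- c(1L, dims[1], if (length(dims) == 3L) dims[1] * dims[2])
  nextlab <- 0L
  todo <- which(cells)
  co <- arrayInd(seq_along(cells), dims)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    nextlab <- nextlab + 1L
    frontier <- seed
    lab[seed] <- nextlab
    while (length(frontier)) {
      nxt <- integer(0)
      for (a in seq_along(strides)) {
        for (sgn in c(1L, -1L)) {
          cand <- frontier + sgn * strides[a]
          ok <- cand >= 1L & cand <= length(cells)
          cand <- cand[ok]; from <- frontier[ok]
          # reject wrap-around across the grid edge
          keep <- co[cand, a] - co[from, a] == sgn
          cand <- cand[keep]
          cand <- cand[cells[cand] & lab[cand] == 0L]
          lab[cand] <- nextlab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Track a droplet in a concentration field
#'
#' Thresholds the droplet-phase fraction, labels its connected components and
#' reports the trailing edge (minimum path coordinate), the extent along the
#' path, the component count, and the branch occupancy.
#'
#' @param alpha droplet-phase fraction field (ncell).
#' @param mask bifurcation \code{"mf_mask"}.
#' @param threshold phase threshold in (0, 1); default 0.5.
#' @param min_cells components smaller than this are counted as
#'   sub-resolution debris (stray interface cells, condensation specks) and
#'   excluded from the metrics.
#' @return one-row data frame: \code{s_um} (trailing edge of the main
#'   droplet), \code{length_um} (its extent along the path),
#'   \code{n_components} (count of above-threshold components),
#'   \code{branch} ("inlet", "top" or "bottom" — where the main droplet's
#'   leading cells sit).
#' @export
droplet_track <- function(alpha, mask, threshold = 0.5, min_cells = 8L) {
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  cells <- alpha >= threshold & mask$role == MF_ROLES[["fluid"]]
  if (!any(cells)) stop("droplet phase is empty at this threshold")
  s <- bifurcation_path_coordinate(mask)
  lab <- label_components(cells, mask$dims)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_cells)
  if (length(keep) == 0L) keep <- which.max(sizes)
  main <- keep[which.max(sizes[keep])]
  body <- lab == main
  j <- attr(mask, "junction")
  co <- arrayInd(seq_len(prod(mask$dims)), mask$dims)
  yc <- (j$ylo + j$yhi) / 2 + 1
  lead <- which(body)[which.max(s[body])]
  branch <- if (co[lead, 1] - 1L <= j$nl) "inlet"
            else if (co[lead, 2] > yc) "top" else "bottom"
  data.frame(s_um = min(s[body]) * 1e6,
             length_um = (max(s[body]) - min(s[body])) * 1e6,
             n_components = length(keep),
             branch = branch)
}
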