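#' Write fields as a legacy VTK structured-points file
#'
#' ASCII legacy VTK, STRUCTURED_POINTS dataset; one SCALARS block per field
#' plus an optional VECTORS block for a velocity field. Suitable for ParaView
#' and other standard viewers.
#'
#' @param path output file.
#' @param dims grid dimensions (2 or 3 long; 2D grids are written with one
#'   z-plane).
#' @param dx cell spacing (m); written in micrometres for readability.
#' @param scalars named list of numeric cell fields (ncell each).
#' @param vectors optional named list of \code{ncell x d} matrices.
#' @return the path, invisibly.
#' @export
write_vtk <- function(path, dims, dx, scalars = list(), vectors = list()) {
  d3 <- c(dims, 1L, 1L)[1:3]
  n <- prod(d3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "mfsim field dump",
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d3[1], d3[2], d3[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %.9g %.9g %.9g", dx * 1e6, dx * 1e6, dx * 1e6),
               sprintf("POINT_DATA %d", n)), con)
  for (nm in names(scalars)) {
    stopifnot(length(scalars[[nm]]) == n)
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(formatC(scalars[[nm]], format = "g", digits = 9), con)
  }
  for (nm in names(vectors)) {
    v <- vectors[[nm]]
    if (ncol(v) == 2L) v <- cbind(v, 0)
    stopifnot(nrow(v) == n)
    writeLines(sprintf("VECTORS %s double", nm), con)
    writeLines(paste(formatC(v[, 1], format = "g", digits = 9),
                     formatC(v[, 2], format = "g", digits = 9),
                     formatC(v[, 3], format = "g", digits = 9)), con)
  }
  invisible(path)
}

#' Structural check of a VTK structured-points file
#'
#' Validates header keywords and that the declared extent matches the number
#' of data values of each block.
#' @param path file to check.
#' @return \code{TRUE} (or an error describing the inconsistency).
#' @export
validate_vtk <- function(path) {
  ln <- readLines(path)
  if (ln[1] != "# vtk DataFile Version 3.0") stop("bad VTK header")
  if (!"ASCII" %in% ln[3]) stop("expected ASCII VTK")
  if (ln[4] != "DATASET STRUCTURED_POINTS") stop("expected STRUCTURED_POINTS")
  dims <- as.integer(strsplit(ln[5], " ")[[1]][-1])
  n <- prod(dims)
  pd <- as.integer(strsplit(grep("^POINT_DATA", ln, value = TRUE)[1], " ")[[1]][2])
  if (pd != n) stop("POINT_DATA count does not match DIMENSIONS")
  sc <- grep("^SCALARS", ln)
  for (s in sc) {
    vals <- ln[(s + 2):(s + 1 + n)]
    if (anyNA(suppressWarnings(as.numeric(vals)))) stop("non-numeric scalar data block")
  }
  TRUE
}

#' Write a profile to CSV
#'
#' Velocity profiles are written as (\code{position_um}, \code{velocity_mm_s});
#' concentration profiles as (\code{position_um}, \code{concentration});
#' trajectories as (\code{time_ms}, \code{s_um}).
#'
#' @param x an \code{"mf_profile"}, \code{"mf_conc_profile"},
#'   \code{"mf_trajectory"} or plain data frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_profile_csv <- function(x, path) {
  df <- if (inherits(x, "mf_profile")) {
    data.frame(position_um = x$z * 1e6, velocity_mm_s = x$u * 1e3)
  } else if (inherits(x, "mf_conc_profile")) {
    data.frame(position_um = x$z * 1e6, concentration = x$alpha)
  } else if (inherits(x, "mf_trajectory")) {
    data.frame(time_ms = x$t * 1e3, s_um = x$s * 1e6)
  } else as.data.frame(x)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run report as JSON
#'
#' @param report named list (metrics, configuration echo, step counts, ...).
#' @param path output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the outputs of a use-case run
#'
#' Deterministic file naming: \code{<case>_<level>_<hash>_<what>.<ext>} inside
#' \code{out_dir}, where the hash is a short digest of the configuration echo.
#'
#' @param result an \code{"mf_result"} from \code{\link{run_use_case}}.
#' @param out_dir writable output directory (created if absent).
#' @return character vector of the files written.
#' @export
write_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stem <- file.path(out_dir, sprintf("%s_%s_%s", result$case, result$level, result$config_hash))
  files <- character(0)
  if (!is.null(result$profile)) {
    files <- c(files, write_profile_csv(result$profile, paste0(stem, "_profile.csv")))
  }
  if (!is.null(result$trajectory)) {
    files <- c(files, write_profile_csv(result$trajectory, paste0(stem, "_trajectory.csv")))
  }
  if (!is.null(result$track)) {
    tr <- paste0(stem, "_track.csv")
    utils::write.csv(result$track, tr, row.names = FALSE)
    files <- c(files, tr)
  }
  if (!is.null(result$fields)) {
    vtk <- paste0(stem, "_fields.vtk")
    write_vtk(vtk, result$fields$dims, result$fields$dx,
              scalars = result$fields$scalars, vectors = result$fields$vectors)
    files <- c(files, vtk)
  }
  rep <- paste0(stem, "_report.json")
  write_report_json(result$report, rep)
  c(files, rep)
}

# short deterministic hash of a configuration echo (no external digest dep)
config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(cfg, digits.d = 12)), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^28
  sprintf("%07x", h)
}
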