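#' Leaflet point cloud
#'
#' Labeled 3D points (Angstrom) sampled on one membrane leaflet.
#'
#' @param coords numeric N x 3 matrix or data.frame with columns x, y, z.
#' @param leaflet \code{"upper"} (cytosolic) or \code{"lower"} (lumenal).
#' @param provenance free-text origin of the points.
#' @return a data.frame of class \code{leaflet_cloud} with columns x, y, z
#'   and attributes \code{leaflet} and \code{provenance}.
#' @export
leaflet_cloud <- function(coords, leaflet = c("upper", "lower"),
                          provenance = "") {
  leaflet <- match.arg(leaflet)
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stop("coords must have 3 columns (x, y, z)")
  if (nrow(coords) < 1) stop("a leaflet cloud needs at least one point")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  df <- data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  attr(df, "leaflet") <- leaflet
  attr(df, "provenance") <- provenance
  class(df) <- c("leaflet_cloud", "data.frame")
  df
}

#' @export
print.leaflet_cloud <- function(x, ...) {
  cat(sprintf("leaflet_cloud: %d points, leaflet = %s\n",
              nrow(x), attr(x, "leaflet")))
  invisible(x)
}

#' Regular lateral grid specification
#'
#' @param x_range,y_range length-2 numeric intervals (Angstrom).
#' @param spacing grid spacing in Angstrom (default 4, about the voxel
#'   scale of a binned cryo-ET map).
#' @return an object of class \code{grid_spec} with node coordinate
#'   vectors \code{x} and \code{y}.
#' @export
grid_spec <- function(x_range, y_range, spacing = 4) {
  if (spacing <= 0) stop("spacing must be > 0")
  if (diff(x_range) <= 0 || diff(y_range) <= 0)
    stop("ranges must be non-degenerate")
  structure(list(x_range = as.numeric(x_range),
                 y_range = as.numeric(y_range),
                 spacing = spacing,
                 x = seq(x_range[1], x_range[2], by = spacing),
                 y = seq(y_range[1], y_range[2], by = spacing)),
            class = "grid_spec")
}

#' Grid spec covering a point cloud
#'
#' @param points a \code{leaflet_cloud} or anything with x/y columns.
#' @param spacing grid spacing (Angstrom).
#' @param shrink margin (Angstrom) trimmed from each side, keeping nodes
#'   inside the convex hull of typical uniform samples.
#' @return a \code{grid_spec}.
#' @export
grid_for_points <- function(points, spacing = 4, shrink = 0) {
  grid_spec(range(points$x) + c(shrink, -shrink),
            range(points$y) + c(shrink, -shrink), spacing)
}

new_field <- function(grid, z, valid, class2) {
  stopifnot(inherits(grid, "grid_spec"))
  nx <- length(grid$x); ny <- length(grid$y)
  stopifnot(all(dim(z) == c(nx, ny)), all(dim(valid) == c(nx, ny)))
  z[!valid] <- NA_real_
  structure(list(grid = grid, z = z, valid = valid),
            class = c(class2, "mem_field"))
}

#' Height field: surface heights z(x, y) on a regular grid
#'
#' @param grid a \code{grid_spec}.
#' @param z numeric matrix, \code{length(grid$x)} x \code{length(grid$y)}.
#' @param valid logical matrix of the same shape; invalid cells carry NA.
#' @return an object of class \code{height_field}.
#' @export
height_field <- function(grid, z, valid = is.finite(z)) {
  new_field(grid, z, valid, "height_field")
}

#' Scalar map: per-grid-cell derived quantity
#'
#' Same layout as \code{\link{height_field}}; \code{unit} records the
#' physical unit (e.g. "1/A" for curvature, "A" for thickness).
#'
#' @inheritParams height_field
#' @param unit unit string.
#' @return an object of class \code{scalar_map}.
#' @export
scalar_map <- function(grid, z, valid = is.finite(z), unit = "") {
  f <- new_field(grid, z, valid, "scalar_map")
  f$unit <- unit
  f
}

#' @export
print.mem_field <- function(x, ...) {
  cat(sprintf("%s: %d x %d grid, spacing %g A, %d valid cells\n",
              class(x)[1], length(x$grid$x), length(x$grid$y),
              x$grid$spacing, sum(x$valid)))
  invisible(x)
}

#' Grid-node lateral coordinates of a field
#'
#' @param field a \code{height_field} or \code{scalar_map}.
#' @return list with matrices \code{x} and \code{y} matching \code{field$z}.
#' @export
field_xy <- function(field) {
  g <- field$grid
  list(x = outer(g$x, rep(1, length(g$y))),
       y = outer(rep(1, length(g$x)), g$y))
}

#' Atom model
#'
#' Minimal per-atom table for structure analyses (SASA, interfaces,
#' selections): element, atom name, residue id, chain, coordinates and van
#' der Waals radius.
#'
#' @param df data.frame with columns \code{element}, \code{name},
#'   \code{resid}, \code{resname}, \code{chain}, \code{x}, \code{y},
#'   \code{z}; a \code{radius} column is added from the Bondi table if
#'   missing.
#' @param default_radius radius (Angstrom) assigned, with a warning, to
#'   elements absent from the table.
#' @return a data.frame of class \code{atom_model}.
#' @export
atom_model <- function(df, default_radius = 1.5) {
  req <- c("element", "name", "resid", "chain", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("atom_model needs columns: ", paste(req, collapse = ", "))
  if (is.null(df$resname)) df$resname <- "UNK"
  if (is.null(df$radius)) {
    df$radius <- vdw_radius(df$element, default_radius = default_radius)
  }
  if (any(df$radius <= 0)) stop("van der Waals radii must be > 0")
  class(df) <- c("atom_model", "data.frame")
  df
}

#' Lipid / protein trajectory
#'
#' Time-ordered coordinate frames with constant atom annotations. The
#' coordinate array is \code{n_atoms x 3 x n_frames} (Angstrom).
#'
#' @param coords numeric array \code{n_atoms x 3 x n_frames}.
#' @param atoms data.frame of per-atom annotations (at minimum \code{name};
#'   lipid analyses additionally use \code{lipid} id, \code{role} in
#'   \{head, C, H\}, \code{carbon} index and \code{leaflet}).
#' @param box per-frame box, 3 x n_frames matrix or length-3 vector.
#' @param time frame time stamps, strictly increasing.
#' @return an object of class \code{lipid_trajectory}.
#' @export
lipid_trajectory <- function(coords, atoms, box = NULL,
                             time = seq_len(dim(coords)[3])) {
  d <- dim(coords)
  if (length(d) != 3 || d[2] != 3)
    stop("coords must be an n_atoms x 3 x n_frames array")
  if (nrow(atoms) != d[1])
    stop("atom annotation rows must match the coordinate count")
  if (length(time) != d[3] || any(diff(time) <= 0))
    stop("time stamps must be strictly increasing, one per frame")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, 3, d[3])
    stopifnot(all(dim(box) == c(3, d[3])))
  }
  structure(list(coords = coords, atoms = atoms, box = box, time = time),
            class = "lipid_trajectory")
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  cat(sprintf("lipid_trajectory: %d atoms, %d frames\n",
              dim(x$coords)[1], dim(x$coords)[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a \code{lipid_trajectory}.
#' @return integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Flip-flop event log
#'
#' @param events data.frame with columns \code{lipid}, \code{frame},
#'   \code{direction} ("up" or "down") and optionally lateral position
#'   columns \code{x}, \code{y}.
#' @param n_frames total frame count, for the cumulative curve.
#' @return an object of class \code{event_log} with a non-decreasing
#'   \code{cumulative} curve (events vs frame).
#' @export
event_log <- function(events, n_frames) {
  if (nrow(events) > 0) {
    events <- events[order(events$frame, events$lipid), , drop = FALSE]
    if (any(events$frame < 1 | events$frame > n_frames))
      stop("event frames outside trajectory range")
  }
  cum <- cumsum(tabulate(events$frame, nbins = n_frames))
  structure(list(events = events, n_frames = n_frames, cumulative = cum),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("event_log: %d flip-flop events over %d frames\n",
              nrow(x$events), x$n_frames))
  invisible(x)
}
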