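#' LOESS configuration for leaflet smoothing
#'
#' Local regression settings: each grid node is fitted with a bivariate
#' polynomial over its \code{ceiling(span_fraction * N)} nearest data points,
#' weighted by the tricube kernel w = (1 - (d / d_max)^3)^3. The defaults
#' (20\% of the data points, quadratic polynomials) follow the published
#' membrane-surface protocol.
#'
#' @param span_fraction fraction of the data points entering each local fit,
#'   in (0, 1]. Default 0.20.
#' @param degree polynomial degree, 1 or 2. Default 2.
#' @param robustness_iters reserved; only 0 is implemented.
#' @param cond_max condition-number guard: a local quadratic fit whose
#'   normal-equation condition number exceeds this is downgraded to degree 1
#'   (robustness at hull edges).
#' @return an object of class \code{loess_config}.
#' @export
loess_config <- function(span_fraction = 0.20, degree = 2,
                         robustness_iters = 0, cond_max = 1e10) {
  if (span_fraction <= 0 || span_fraction > 1)
    stop("span_fraction must lie in (0, 1]")
  if (!degree %in% c(1, 2)) stop("degree must be 1 or 2")
  if (robustness_iters != 0)
    stop("robustness iterations are not implemented")
  structure(list(span_fraction = span_fraction, degree = as.integer(degree),
                 weight_kernel = "tricube",
                 robustness_iters = 0L, cond_max = cond_max),
            class = "loess_config")
}

#' Piecewise-linear scattered interpolation onto a regular grid
#'
#' Interpolates z over the Delaunay triangulation of the lateral (x, y)
#' positions; grid cells outside the convex hull are marked invalid.
#' Triangulation and barycentric interpolation are delegated to
#' \pkg{interp}.
#'
#' @param points a \code{\link{leaflet_cloud}} (or data.frame with x, y, z).
#' @param grid a \code{\link{grid_spec}}.
#' @return a \code{\link{height_field}}.
#' @export
interpolate_scattered <- function(points, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(points) < 3)
    stop("triangulation error: need at least 3 points")
  # collinearity check after projection to the lateral plane
  xy <- cbind(points$x, points$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2)
    stop("triangulation error: lateral positions are collinear")
  res <- tryCatch(
    interp::interp(x = points$x, y = points$y, z = points$z,
                   xo = grid$x, yo = grid$y, method = "linear",
                   duplicate = "mean"),
    error = function(e) stop("triangulation error: ", conditionMessage(e)))
  height_field(grid, res$z, is.finite(res$z))
}

# design matrix for a bivariate polynomial centered at the node
poly_design <- function(dx, dy, degree) {
  if (degree == 1) cbind(1, dx, dy)
  else cbind(1, dx, dy, dx * dx, dx * dy, dy * dy)
}

#' LOESS smoothing of a height field or point set
#'
#' Classical LOESS generalized to two lateral dimensions: at each output
#' grid node, a degree-1 or degree-2 bivariate polynomial is fitted by
#' weighted least squares to the k nearest data points
#' (k = ceiling(span_fraction * N), tricube weights) and evaluated at the
#' node. Nodes whose local system is rank-deficient are marked invalid; a
#' quadratic fit with an ill-conditioned normal matrix is downgraded to
#' degree 1 (see \code{\link{loess_config}}).
#'
#' @param x a \code{\link{height_field}} (its valid cells are the data) or a
#'   point set with x, y, z columns.
#' @param cfg a \code{\link{loess_config}}.
#' @param grid output \code{\link{grid_spec}}; defaults to the input field's
#'   grid (required when \code{x} is a point set).
#' @return a \code{\link{height_field}} on \code{grid}.
#' @export
loess_smooth <- function(x, cfg = loess_config(), grid = NULL) {
  if (inherits(x, "height_field")) {
    if (is.null(grid)) grid <- x$grid
    xy <- field_xy(x)
    keep <- as.logical(x$valid)
    data <- cbind(as.numeric(xy$x)[keep], as.numeric(xy$y)[keep])
    zd <- as.numeric(x$z)[keep]
  } else {
    if (is.null(grid)) stop("grid must be given for point-set input")
    data <- cbind(x$x, x$y)
    zd <- x$z
  }
  n <- nrow(data)
  p <- if (cfg$degree == 2) 6L else 3L
  k <- max(p, ceiling(cfg$span_fraction * n))
  if (n < p) stop("too few points (", n, ") for a degree-", cfg$degree,
                  " local fit")
  k <- min(k, n)
  nodes <- as.matrix(expand.grid(x = grid$x, y = grid$y))
  nn <- FNN::get.knnx(data, nodes, k = k)
  zfit <- rep(NA_real_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    idx <- nn$nn.index[i, ]
    d <- nn$nn.dist[i, ]
    dmax <- d[k]
    w <- if (dmax > 0) (1 - pmin(d / dmax, 1)^3)^3 else rep(1, k)
    # keep the farthest point's zero weight from annihilating the fit
    pos <- w > 0
    if (sum(pos) < p) { w <- w + 1e-12; pos <- w > 0 }
    dx <- data[idx, 1] - nodes[i, 1]
    dy <- data[idx, 2] - nodes[i, 2]
    zfit[i] <- local_wls(dx[pos], dy[pos], zd[idx][pos], w[pos],
                         cfg$degree, cfg$cond_max)
  }
  z <- matrix(zfit, length(grid$x), length(grid$y))
  height_field(grid, z, is.finite(z))
}

# weighted least squares of a centered bivariate polynomial; returns the
# fitted value at the center (the intercept), or NA if rank-deficient
local_wls <- function(dx, dy, z, w, degree, cond_max) {
  fit_deg <- function(deg) {
    X <- poly_design(dx, dy, deg)
    sw <- sqrt(w)
    Xw <- X * sw
    A <- crossprod(Xw)
    b <- crossprod(Xw, z * sw)
    list(A = A, b = b)
  }
  sys <- fit_deg(degree)
  if (degree == 2) {
    ok <- is.finite(rcond(sys$A)) && rcond(sys$A) > 1 / cond_max
    if (!ok) sys <- fit_deg(1)
  }
  beta <- tryCatch(solve(sys$A, sys$b), error = function(e) NULL)
  if (is.null(beta) && degree == 2) {
    sys <- fit_deg(1)
    beta <- tryCatch(solve(sys$A, sys$b), error = function(e) NULL)
  }
  if (is.null(beta)) NA_real_ else beta[1]
}

#' Fit a smooth leaflet surface from scattered points
#'
#' The canonical two-step surface operation: piecewise-linear Delaunay
#' interpolation onto the grid (\code{\link{interpolate_scattered}})
#' followed by LOESS local regression on the gridded samples
#' (\code{\link{loess_smooth}}), removing the discreteness of the
#' extracted coordinates.
#'
#' @param points a \code{\link{leaflet_cloud}}.
#' @param grid a \code{\link{grid_spec}}; default covers the points at 4 A
#'   spacing.
#' @param cfg a \code{\link{loess_config}}.
#' @return a \code{\link{height_field}}.
#' @export
fit_leaflet <- function(points, grid = grid_for_points(points),
                        cfg = loess_config()) {
  raw <- interpolate_scattered(points, grid)
  sm <- loess_smooth(raw, cfg)
  # LOESS extrapolates beyond the hull; keep only cells the triangulation
  # covered so the field's support matches the data
  sm$valid <- sm$valid & raw$valid
  sm$z[!sm$valid] <- NA_real_
  sm
}

#' Time-averaged head-group (phosphate) height field from a trajectory
#'
#' Averages the head reference-particle z over all frames and lipids per
#' lateral grid cell, per leaflet: the trajectory analogue of a leaflet
#' surface. Cells with no samples are invalid.
#'
#' @param traj a \code{\link{lipid_trajectory}} whose atoms table has
#'   \code{role == "head"} rows.
#' @param leaflet "upper" or "lower"; lipids are assigned per frame by the
#'   sign of head z relative to \code{midplane}.
#' @param grid a \code{\link{grid_spec}}.
#' @param midplane membrane midplane height (Angstrom), default 0.
#' @return a \code{\link{height_field}}.
#' @export
phosphate_height_field <- function(traj, leaflet = c("upper", "lower"),
                                   grid, midplane = 0) {
  leaflet <- match.arg(leaflet)
  heads <- which(traj$atoms$role == "head")
  if (length(heads) == 0) stop("selection error: no head particles in trajectory")
  nf <- n_frames(traj)
  hx <- as.numeric(traj$coords[heads, 1, ])
  hy <- as.numeric(traj$coords[heads, 2, ])
  hz <- as.numeric(traj$coords[heads, 3, ])
  keep <- if (leaflet == "upper") hz > midplane else hz <= midplane
  if (!any(keep)) stop("selection error: no heads in the requested leaflet")
  ix <- findInterval(hx[keep], grid$x - grid$spacing / 2)
  iy <- findInterval(hy[keep], grid$y - grid$spacing / 2)
  nx <- length(grid$x); ny <- length(grid$y)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  cell <- ix[ok] + nx * (iy[ok] - 1)
  zsum <- rowsum(hz[keep][ok], cell)
  cnt <- rowsum(rep(1, sum(ok)), cell)
  z <- matrix(NA_real_, nx, ny)
  z[as.integer(rownames(zsum))] <- zsum / cnt
  height_field(grid, z, is.finite(z))
}
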