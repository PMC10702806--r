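# first derivative along matrix rows (x direction), central differences with
# one-sided stencils at valid-mask borders; NA where no neighbor is usable
fd_x <- function(z, h) {
  nx <- nrow(z); ny <- ncol(z)
  out <- matrix(NA_real_, nx, ny)
  zp <- rbind(z[-1, , drop = FALSE], NA)      # z[i+1, j]
  zm <- rbind(NA, z[-nx, , drop = FALSE])     # z[i-1, j]
  ctr <- (zp - zm) / (2 * h)
  fwd <- (zp - z) / h
  bwd <- (z - zm) / h
  out[] <- ifelse(is.finite(ctr), ctr, ifelse(is.finite(fwd), fwd, bwd))
  out
}

fd_y <- function(z, h) t(fd_x(t(z), h))

# second derivative along rows; central (3-point) where possible, else
# one-sided 3-point
fd_xx <- function(z, h) {
  nx <- nrow(z)
  zp <- rbind(z[-1, , drop = FALSE], NA)
  zm <- rbind(NA, z[-nx, , drop = FALSE])
  zpp <- rbind(z[-(1:2), , drop = FALSE], NA, NA)
  zmm <- rbind(NA, NA, z[-((nx - 1):nx), , drop = FALSE])
  ctr <- (zp - 2 * z + zm) / h^2
  fwd <- (zpp - 2 * zp + z) / h^2
  bwd <- (z - 2 * zm + zmm) / h^2
  ifelse(is.finite(ctr), ctr, ifelse(is.finite(fwd), fwd, bwd))
}

fd_yy <- function(z, h) t(fd_xx(t(z), h))

field_derivs <- function(field) {
  h <- field$grid$spacing
  z <- field$z
  zx <- fd_x(z, h); zy <- fd_y(z, h)
  list(zx = zx, zy = zy,
       zxx = fd_xx(z, h), zyy = fd_yy(z, h),
       zxy = fd_y(zx, h))
}

check_region_size <- function(field) {
  v <- field$valid
  # require at least a 3x3 block of valid cells somewhere
  if (nrow(v) < 3 || ncol(v) < 3 ||
      !any(v[-c(1, nrow(v)), -c(1, ncol(v))] &
           v[-((nrow(v) - 1):nrow(v)), -c(1, ncol(v))] &
           v[-(1:2), -c(1, ncol(v))] &
           v[-c(1, nrow(v)), -((ncol(v) - 1):ncol(v))] &
           v[-c(1, nrow(v)), -(1:2)]))
    stop("geometry error: valid region smaller than 3x3 cells")
  invisible(TRUE)
}

#' Mean curvature map of a height field
#'
#' H = [(1 + z_x^2) z_yy - 2 z_x z_y z_xy + (1 + z_y^2) z_xx] /
#' [2 (1 + z_x^2 + z_y^2)^(3/2)], evaluated with central finite differences
#' (one-sided at valid-mask borders). Sign convention: the surface normal
#' points toward +z (the cytosolic side), so a bulge toward +z has negative
#' mean curvature at its apex; a sphere cap of radius R has H = -1/R.
#'
#' @param field a \code{\link{height_field}} valid on a connected region of
#'   at least 3 x 3 cells.
#' @return a \code{\link{scalar_map}} (unit 1/Angstrom).
#' @export
mean_curvature_map <- function(field) {
  stopifnot(inherits(field, "height_field"))
  check_region_size(field)
  d <- field_derivs(field)
  H <- ((1 + d$zx^2) * d$zyy - 2 * d$zx * d$zy * d$zxy +
          (1 + d$zy^2) * d$zxx) /
    (2 * (1 + d$zx^2 + d$zy^2)^1.5)
  scalar_map(field$grid, H, is.finite(H) & field$valid, unit = "1/A")
}

#' Gaussian curvature map of a height field
#'
#' K = (z_xx z_yy - z_xy^2) / (1 + z_x^2 + z_y^2)^2, same differencing and
#' masking as \code{\link{mean_curvature_map}}.
#'
#' @inheritParams mean_curvature_map
#' @return a \code{\link{scalar_map}} (unit 1/Angstrom^2).
#' @export
gaussian_curvature_map <- function(field) {
  stopifnot(inherits(field, "height_field"))
  check_region_size(field)
  d <- field_derivs(field)
  K <- (d$zxx * d$zyy - d$zxy^2) / (1 + d$zx^2 + d$zy^2)^2
  scalar_map(field$grid, K, is.finite(K) & field$valid, unit = "1/A^2")
}

#' Regional radius of curvature from a mean-curvature map
#'
#' R = 1 / |mean(H over region)|. Averaging H before inverting (rather than
#' averaging 1/|H|) is stable when H fluctuates around small values. The
#' signed region-mean H is reported alongside.
#'
#' @param cmap a mean-curvature \code{\link{scalar_map}}.
#' @param center lateral region center (x, y) in Angstrom; default the grid
#'   center.
#' @param radius region radius (Angstrom); \code{Inf} uses all valid cells.
#' @param exclude_radius optional inner radius; cells closer than this to
#'   \code{center} are excluded (for far-field estimates around a feature).
#' @return list with \code{radius} (Angstrom; \code{Inf} when the mean
#'   curvature is zero), \code{mean_H} (signed, 1/Angstrom) and \code{n}
#'   cells used.
#' @export
radius_of_curvature <- function(cmap, center = NULL, radius = Inf,
                                exclude_radius = 0) {
  stopifnot(inherits(cmap, "scalar_map"))
  xy <- field_xy(cmap)
  if (is.null(center))
    center <- c(mean(range(cmap$grid$x)), mean(range(cmap$grid$y)))
  r <- sqrt((xy$x - center[1])^2 + (xy$y - center[2])^2)
  sel <- cmap$valid & r <= radius & r >= exclude_radius
  if (!any(sel)) stop("region contains no valid cells")
  mH <- mean(cmap$z[sel])
  list(radius = if (mH == 0) Inf else 1 / abs(mH), mean_H = mH, n = sum(sel))
}

#' Least-squares sphere fit
#'
#' Algebraic linear least-squares fit (Coope formulation: minimize
#' ||p - c||^2 - R^2 over center and radius via a linear system) refined by
#' one Gauss-Newton pass on the geometric residuals |p - c| - R.
#'
#' @param x a \code{\link{leaflet_cloud}}, an N x 3 matrix, or a
#'   \code{\link{height_field}} (its valid cells are used as points).
#' @param gn_iters Gauss-Newton refinement passes (default 1).
#' @return an object of class \code{sphere_fit}: list with \code{center},
#'   \code{radius} (Angstrom) and \code{rms_residual} (Angstrom).
#' @export
fit_sphere <- function(x, gn_iters = 1) {
  if (inherits(x, "height_field")) {
    xy <- field_xy(x)
    keep <- as.logical(x$valid)
    P <- cbind(as.numeric(xy$x)[keep], as.numeric(xy$y)[keep],
               as.numeric(x$z)[keep])
  } else if (is.data.frame(x)) {
    P <- as.matrix(x[, c("x", "y", "z")])
  } else P <- as.matrix(x)
  if (nrow(P) < 4) stop("degenerate-fit error: need at least 4 points")
  if (qr(sweep(P, 2, colMeans(P)))$rank < 3)
    stop("degenerate-fit error: points are coplanar")
  B <- cbind(2 * P, 1)
  f <- rowSums(P^2)
  a <- tryCatch(qr.solve(B, f),
                error = function(e) stop("degenerate-fit error: ",
                                         conditionMessage(e)))
  ctr <- unname(a[1:3])
  R <- unname(sqrt(a[4] + sum(ctr^2)))
  for (it in seq_len(gn_iters)) {
    dv <- sweep(P, 2, ctr)
    dist <- sqrt(rowSums(dv^2))
    res <- dist - R
    J <- cbind(-dv / dist, -1)           # d res / d (center, R)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    ctr <- ctr + unname(step[1:3])
    R <- R + unname(step[4])
  }
  dist <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  structure(list(center = ctr, radius = R,
                 rms_residual = sqrt(mean((dist - R)^2))),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf("sphere_fit: R = %.2f A, center (%.2f, %.2f, %.2f), rms %.3g A\n",
              x$radius, x$center[1], x$center[2], x$center[3],
              x$rms_residual))
  invisible(x)
}
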