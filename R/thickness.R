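#' Membrane thickness map from paired leaflet fields
#'
#' Thickness = z_upper - z_lower per grid cell, valid where both fields are.
#' If the grids differ, the lower field is resampled onto the upper field's
#' grid by bilinear interpolation before differencing.
#'
#' @param upper,lower \code{\link{height_field}}s for the cytosolic and
#'   lumenal leaflet.
#' @return a \code{\link{scalar_map}} (unit Angstrom).
#' @export
thickness_map <- function(upper, lower) {
  stopifnot(inherits(upper, "height_field"), inherits(lower, "height_field"))
  if (!isTRUE(all.equal(upper$grid[c("x", "y")], lower$grid[c("x", "y")])))
    lower <- resample_field(lower, upper$grid)
  th <- upper$z - lower$z
  valid <- upper$valid & lower$valid & is.finite(th)
  if (!any(valid))
    stop("empty-map error: leaflet fields have disjoint valid regions")
  scalar_map(upper$grid, th, valid, unit = "A")
}

# bilinear resampling of a height field onto a new grid
resample_field <- function(field, grid) {
  gx <- field$grid$x; gy <- field$grid$y
  z <- field$z
  nx <- length(gx); ny <- length(gy)
  pts <- expand.grid(x = grid$x, y = grid$y)
  ix <- findInterval(pts$x, gx, rightmost.closed = TRUE)
  iy <- findInterval(pts$y, gy, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
  out <- rep(NA_real_, nrow(pts))
  i <- ix[ok]; j <- iy[ok]
  tx <- (pts$x[ok] - gx[i]) / (gx[i + 1] - gx[i])
  ty <- (pts$y[ok] - gy[j]) / (gy[j + 1] - gy[j])
  z11 <- z[cbind(i, j)];     z21 <- z[cbind(i + 1, j)]
  z12 <- z[cbind(i, j + 1)]; z22 <- z[cbind(i + 1, j + 1)]
  out[ok] <- (1 - tx) * (1 - ty) * z11 + tx * (1 - ty) * z21 +
    (1 - tx) * ty * z12 + tx * ty * z22
  zc <- matrix(out, length(grid$x), length(grid$y))
  height_field(grid, zc, is.finite(zc))
}

#' Profile of leaflet height along a lateral axis
#'
#' Projects lateral positions onto the axis through \code{origin} with unit
#' direction \code{direction}, bins the projected coordinate, and averages z
#' per bin (per leaflet when a list of two point sets is given). Mirrors the
#' vertical-shift profiles computed parallel and perpendicular to the axis
#' connecting two membrane proteins.
#'
#' @param points a \code{\link{leaflet_cloud}} / data.frame with x, y, z, or
#'   a \code{\link{height_field}} (valid cells are used).
#' @param direction lateral direction (length-2), normalized internally.
#' @param origin lateral origin (length-2), default c(0, 0).
#' @param bin_width bin width (Angstrom).
#' @return data.frame of class \code{axis_profile} with columns
#'   \code{center} (projected coordinate of bin center), \code{mean_z},
#'   \code{sd_z}, \code{n}.
#' @export
axis_profile <- function(points, direction, origin = c(0, 0), bin_width = 5) {
  if (sum(direction^2) == 0) stop("parameter error: zero-length axis")
  if (bin_width <= 0) stop("parameter error: bin_width must be > 0")
  u <- direction / sqrt(sum(direction^2))
  if (inherits(points, "height_field") || inherits(points, "scalar_map")) {
    xy <- field_xy(points)
    keep <- as.logical(points$valid)
    x <- as.numeric(xy$x)[keep]; y <- as.numeric(xy$y)[keep]
    z <- as.numeric(points$z)[keep]
  } else {
    x <- points$x; y <- points$y; z <- points$z
  }
  s <- (x - origin[1]) * u[1] + (y - origin[2]) * u[2]
  if (length(s) == 0) stop("no samples to profile")
  brk <- seq(floor(min(s) / bin_width) * bin_width,
             ceiling(max(s) / bin_width) * bin_width + bin_width,
             by = bin_width)
  bin <- cut(s, brk, include.lowest = TRUE, labels = FALSE)
  agg <- function(f) as.numeric(tapply(z, factor(bin, seq_len(length(brk) - 1)), f))
  out <- data.frame(center = (brk[-length(brk)] + brk[-1]) / 2,
                    mean_z = agg(mean),
                    sd_z = agg(stats::sd),
                    n = as.integer(
                      table(factor(bin, seq_len(length(brk) - 1)))))
  class(out) <- c("axis_profile", "data.frame")
  out
}

# ---- 1D Gaussian mixture by EM ---------------------------------------------

# k-means++ style seeding of component means
kmeanspp_centers <- function(x, k) {
  centers <- numeric(k)
  centers[1] <- x[sample.int(length(x), 1)]
  if (k > 1) for (j in 2:k) {
    d2 <- vapply(x, function(v) min((v - centers[1:(j - 1)])^2), 0)
    if (all(d2 == 0)) centers[j:k] <- centers[1] else
      centers[j] <- x[sample.int(length(x), 1, prob = d2)]
    if (all(d2 == 0)) break
  }
  centers
}

#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Expectation-maximization with k-means++ initialization of the component
#' means. The log-likelihood is non-decreasing across iterations (asserted
#' internally); convergence when the increase falls below \code{tol}.
#' Components whose standard deviation collapses below 1e-6 times the data
#' standard deviation are pruned with a warning.
#'
#' @param x numeric samples (n >= 10 k).
#' @param k number of components (default 2).
#' @param seed integer seed for the initialization (default 0).
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param max_iter iteration cap.
#' @return an object of class \code{gaussian_mixture}: list with
#'   \code{weights}, \code{means}, \code{sds} (components sorted by
#'   decreasing mean), \code{log_likelihood}, \code{ll_trace}, \code{n_iter},
#'   \code{converged}, \code{bic}.
#' @export
fit_gaussian_mixture <- function(x, k = 2, seed = 0, tol = 1e-8,
                                 max_iter = 500) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 10 * k) stop("need at least 10 k samples (got ", n, ")")
  set.seed(seed)
  mu <- kmeanspp_centers(x, k)
  sdev <- rep(stats::sd(x), k)
  w <- rep(1 / k, k)
  sd_floor <- 1e-6 * stats::sd(x)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sdev[j]),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    if (length(ll_trace) > 0 && ll < ll_old - 1e-8 * abs(ll_old))
      stop("internal error: EM log-likelihood decreased")
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sdev <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    collapsed <- sdev < sd_floor | !is.finite(sdev)
    if (any(collapsed)) {
      warning("pruned ", sum(collapsed),
              " mixture component(s) with collapsed variance")
      keep <- !collapsed
      k <- sum(keep)
      if (k == 0) stop("all components collapsed")
      w <- w[keep] / sum(w[keep]); mu <- mu[keep]; sdev <- sdev[keep]
    }
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  o <- order(mu, decreasing = TRUE)
  n_par <- 3 * k - 1
  structure(list(k = k, weights = w[o], means = mu[o], sds = sdev[o],
                 log_likelihood = ll_trace[length(ll_trace)],
                 ll_trace = ll_trace, n_iter = length(ll_trace),
                 converged = converged,
                 bic = -2 * ll_trace[length(ll_trace)] + n_par * log(n)),
            class = "gaussian_mixture")
}

#' @export
print.gaussian_mixture <- function(x, ...) {
  cat(sprintf("gaussian_mixture: k = %d (%s)\n", x$k,
              if (x$converged) "converged" else "not converged"))
  for (j in seq_len(x$k))
    cat(sprintf("  w = %.3f, mean = %.3f, sd = %.3f\n",
                x$weights[j], x$means[j], x$sds[j]))
  invisible(x)
}

#' Select the number of mixture components by BIC
#'
#' @inheritParams fit_gaussian_mixture
#' @param k_max largest k tried.
#' @return the \code{\link{fit_gaussian_mixture}} result with lowest BIC.
#' @export
fit_gaussian_mixture_auto <- function(x, k_max = 2, seed = 0, tol = 1e-8,
                                      max_iter = 500) {
  fits <- lapply(seq_len(k_max), function(k)
    fit_gaussian_mixture(x, k = k, seed = seed, tol = tol,
                         max_iter = max_iter))
  fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
}

# ---- deuterium order parameters --------------------------------------------

# per-sample P2 of the angle between C-H vectors and the z axis
ch_p2 <- function(traj, carbons) {
  at <- traj$atoms
  h_rows <- which(at$role == "H" & at$carbon %in% carbons)
  if (length(h_rows) == 0)
    stop("annotation error: no chain hydrogens for requested carbons")
  # parent carbon of each H: the closest preceding C row with same carbon/lipid
  c_rows <- which(at$role == "C")
  key_h <- paste(at$lipid[h_rows], at$carbon[h_rows])
  key_c <- paste(at$lipid[c_rows], at$carbon[c_rows])
  parent <- c_rows[match(key_h, key_c)]
  if (anyNA(parent))
    stop("annotation error: hydrogens without a parent carbon")
  nf <- n_frames(traj)
  v <- traj$coords[h_rows, , , drop = FALSE] -
    traj$coords[parent, , , drop = FALSE]
  cz2 <- (v[, 3, ]^2) / (v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
  list(p2 = (3 * cz2 - 1) / 2,               # n_H x n_frames
       carbon = at$carbon[h_rows],
       lipid = at$lipid[h_rows],
       h_rows = h_rows)
}

#' Deuterium order parameters per chain carbon
#'
#' S_CD = <(3 cos^2 theta - 1) / 2> over lipids, frames and H partners,
#' where theta is the angle of each C-H bond to the membrane normal (the z
#' axis). Values lie in [-0.5, 1]. The chain average over the requested
#' carbons is reported; by convention the magnitude is returned in
#' \code{S_CD} with the sign retained in \code{S_CD_signed} (experimental
#' order-parameter plots show |S_CD|).
#'
#' @param traj a \code{\link{lipid_trajectory}} with annotated chain carbons
#'   and hydrogens.
#' @param carbons carbon indices to analyze (default 2:15, the palmitate
#'   carbons reported in membrane simulations).
#' @return an object of class \code{order_profile}: data.frame with columns
#'   \code{carbon}, \code{S_CD}, \code{S_CD_signed}, \code{se}, \code{n};
#'   attributes \code{chain_average} and \code{chain_average_signed}.
#' @export
order_parameters <- function(traj, carbons = 2:15) {
  s <- ch_p2(traj, carbons)
  per_c <- tapply(as.numeric(s$p2), rep(s$carbon, n_frames(traj)), mean)
  per_se <- tapply(as.numeric(s$p2), rep(s$carbon, n_frames(traj)),
                   function(v) stats::sd(v) / sqrt(length(v)))
  per_n <- tapply(as.numeric(s$p2), rep(s$carbon, n_frames(traj)), length)
  carb <- sort(unique(s$carbon))
  out <- data.frame(carbon = carb,
                    S_CD = abs(as.numeric(per_c[as.character(carb)])),
                    S_CD_signed = as.numeric(per_c[as.character(carb)]),
                    se = as.numeric(per_se[as.character(carb)]),
                    n = as.integer(per_n[as.character(carb)]))
  avg <- mean(as.numeric(s$p2))
  attr(out, "chain_average") <- abs(avg)
  attr(out, "chain_average_signed") <- avg
  attr(out, "chain_average_se") <-
    stats::sd(as.numeric(s$p2)) / sqrt(length(s$p2))
  class(out) <- c("order_profile", "data.frame")
  out
}

#' Local order-parameter map
#'
#' Per lateral grid cell, the average S_CD (signed) of the C-H bonds of
#' lipids whose head lies in that cell, optionally restricted to one leaflet.
#' Cells without samples are invalid.
#'
#' @inheritParams order_parameters
#' @param grid a \code{\link{grid_spec}}.
#' @param leaflet NULL (both), "upper" or "lower" (by head z sign relative
#'   to \code{midplane}).
#' @param midplane midplane height (Angstrom).
#' @return a \code{\link{scalar_map}} (dimensionless, signed S_CD).
#' @export
local_order_map <- function(traj, grid, carbons = 2:15, leaflet = NULL,
                            midplane = 0) {
  s <- ch_p2(traj, carbons)
  at <- traj$atoms
  heads <- which(at$role == "head")
  head_of <- heads[match(s$lipid, at$lipid[heads])]
  nf <- n_frames(traj)
  hx <- as.numeric(traj$coords[head_of, 1, ])
  hy <- as.numeric(traj$coords[head_of, 2, ])
  hz <- as.numeric(traj$coords[head_of, 3, ])
  p2 <- as.numeric(s$p2)
  keep <- rep(TRUE, length(p2))
  if (!is.null(leaflet))
    keep <- if (leaflet == "upper") hz > midplane else hz <= midplane
  if (!any(keep)) stop("selection error: no samples in requested leaflet")
  ix <- findInterval(hx[keep], grid$x - grid$spacing / 2)
  iy <- findInterval(hy[keep], grid$y - grid$spacing / 2)
  nx <- length(grid$x); ny <- length(grid$y)
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  cell <- ix[ok] + nx * (iy[ok] - 1)
  ssum <- rowsum(p2[keep][ok], cell)
  cnt <- rowsum(rep(1, sum(ok)), cell)
  z <- matrix(NA_real_, nx, ny)
  z[as.integer(rownames(ssum))] <- ssum / cnt
  scalar_map(grid, z, is.finite(z), unit = "S_CD")
}
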