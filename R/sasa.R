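#' SASA configuration
#'
#' @param probe_radius solvent probe radius (Angstrom, default 1.4, water).
#' @param n_sphere_points quasi-uniform test points per atom sphere
#'   (default 960; >= 32).
#' @param ignore_h drop hydrogens before the calculation (default TRUE;
#'   Bondi-style united radii make this the standard choice and deposited
#'   models often lack hydrogens).
#' @return an object of class \code{sasa_config}.
#' @export
sasa_config <- function(probe_radius = 1.4, n_sphere_points = 960,
                        ignore_h = TRUE) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (n_sphere_points < 32) stop("n_sphere_points must be >= 32")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 ignore_h = ignore_h),
            class = "sasa_config")
}

# quasi-uniform points on the unit sphere (Fibonacci / golden-spiral lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per atom, test points are placed quasi-uniformly on the expanded sphere
#' of radius (r_vdw + probe); the accessible area is the unoccluded fraction
#' of points times 4 pi (r_vdw + probe)^2. A point is occluded if it falls
#' inside any neighboring atom's expanded sphere.
#'
#' @param model an \code{\link{atom_model}} with radii assigned.
#' @param cfg a \code{\link{sasa_config}}.
#' @return numeric vector of per-atom areas (Angstrom^2); total SASA is
#'   \code{sum()} of it.
#' @export
sasa <- function(model, cfg = sasa_config()) {
  stopifnot(inherits(model, "atom_model"))
  if (cfg$ignore_h) model <- model[toupper(model$element) != "H", ,
                                   drop = FALSE]
  n <- nrow(model)
  if (n == 0) stop("no atoms after hydrogen filtering")
  if (any(!is.finite(model$radius)))
    stop("annotation error: missing van der Waals radius")
  xyz <- as.matrix(model[, c("x", "y", "z")])
  R <- model$radius + cfg$probe_radius
  pts <- fibonacci_sphere(cfg$n_sphere_points)
  areas <- numeric(n)
  # neighbor lists: atoms whose expanded spheres can intersect
  maxR <- max(R)
  nb <- FNN::get.knnx(xyz, xyz, k = min(n, 60))
  for (i in seq_len(n)) {
    cand <- nb$nn.index[i, nb$nn.dist[i, ] < R[i] + maxR]
    cand <- cand[cand != i]
    # fall back to a full scan if the capped neighbor list may be incomplete
    if (length(cand) == min(n, 60) - 1 && n > 60) {
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
      cand <- which(d < R[i] + R & seq_len(n) != i)
    } else {
      cand <- cand[sqrt(rowSums(sweep(xyz[cand, , drop = FALSE], 2,
                                      xyz[i, ])^2)) < R[i] + R[cand]]
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in cand) {
      if (!any(free)) break
      d2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- d2 > R[j]^2
    }
    areas[i] <- mean(free) * 4 * pi * R[i]^2
  }
  areas
}

#' Buried interface area between two atom groups
#'
#' Buried SASA = SASA(A alone) + SASA(B alone) - SASA(A and B together).
#' The conventional single-side interface area is half of that; both are
#' reported.
#'
#' @param model an \code{\link{atom_model}}.
#' @param group_a,group_b disjoint, non-empty integer atom-index vectors.
#' @param cfg a \code{\link{sasa_config}}.
#' @return list with \code{buried_half} (Angstrom^2, the conventional
#'   interface area), \code{buried_total}, and the three SASA totals.
#' @export
interface_area <- function(model, group_a, group_b, cfg = sasa_config()) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("selection error: empty group")
  if (length(intersect(group_a, group_b)) > 0)
    stop("selection error: groups overlap")
  sub <- function(idx) {
    m <- model[idx, , drop = FALSE]
    class(m) <- class(model)
    m
  }
  sa <- sum(sasa(sub(group_a), cfg))
  sb <- sum(sasa(sub(group_b), cfg))
  sab <- sum(sasa(sub(sort(c(group_a, group_b))), cfg))
  buried <- sa + sb - sab
  list(buried_half = buried / 2, buried_total = buried,
       sasa_a = sa, sasa_b = sb, sasa_ab = sab)
}
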