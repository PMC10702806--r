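#' Surface specification for the synthetic-membrane generator
#'
#' Describes an analytic leaflet surface z(x, y) to be sampled as a scattered
#' point cloud. Supported geometries:
#' \describe{
#'   \item{plane}{z = z0.}
#'   \item{sphere_cap}{upper cap of a sphere of radius \code{R}, apex at
#'     \code{z0}: z = z0 + sqrt(R^2 - r^2) - R. The lateral extent must be
#'     smaller than 2R so the cap remains a height function.}
#'   \item{gaussian_bump}{z = z0 + A exp(-r^2 / (2 sigma^2)).}
#'   \item{microsome_patch}{a gently curved background sphere of radius
#'     \code{R_bg} carrying a localized Gaussian bump:
#'     z = z0 + sqrt(R_bg^2 - r^2) - R_bg + A exp(-r^2 / (2 sigma^2)).
#'     Emulates a microsome membrane with a protein-induced high-curvature
#'     spot at the center.}
#' }
#'
#' @param kind one of \code{"plane"}, \code{"sphere_cap"},
#'   \code{"gaussian_bump"}, \code{"microsome_patch"}.
#' @param extent lateral box size in Angstrom; points are drawn uniformly in
#'   \code{[-extent/2, extent/2]^2}.
#' @param density points per square Angstrom.
#' @param noise_sd standard deviation (Angstrom) of additive Gaussian noise
#'   on z.
#' @param z0 base height in Angstrom.
#' @param R sphere radius (Angstrom), for \code{sphere_cap}.
#' @param A bump amplitude (Angstrom).
#' @param sigma bump width (Angstrom).
#' @param R_bg background sphere radius (Angstrom), for
#'   \code{microsome_patch}.
#' @param seed integer seed; identical seeds give bit-identical clouds.
#' @return an object of class \code{surface_spec}.
#' @export
surface_spec <- function(kind = c("plane", "sphere_cap", "gaussian_bump",
                                  "microsome_patch"),
                         extent = 100, density = 0.1, noise_sd = 0,
                         z0 = 0, R = NULL, A = NULL, sigma = NULL,
                         R_bg = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(extent) || extent <= 0) stop("extent must be > 0")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (kind == "sphere_cap") {
    if (is.null(R) || R <= 0) stop("sphere_cap requires R > 0")
    # extent/2 in each direction; corner radius must stay below R so the cap
    # is a single-valued height function
    if (extent >= sqrt(2) * R)
      stop("geometry error: sphere cap extent too large for radius R")
  }
  if (kind %in% c("gaussian_bump", "microsome_patch")) {
    if (is.null(A)) A <- 10
    if (is.null(sigma) || sigma <= 0) stop("gaussian bump requires sigma > 0")
  }
  if (kind == "microsome_patch") {
    if (is.null(R_bg) || R_bg <= 0) stop("microsome_patch requires R_bg > 0")
    if (extent >= sqrt(2) * R_bg)
      stop("geometry error: extent too large for background radius R_bg")
  }
  structure(list(kind = kind, extent = extent, density = density,
                 noise_sd = noise_sd, z0 = z0, R = R, A = A, sigma = sigma,
                 R_bg = R_bg, seed = as.integer(seed)),
            class = "surface_spec")
}

#' Bilayer specification (paired leaflet surfaces)
#'
#' @param upper,lower \code{surface_spec} objects for the cytosolic (upper)
#'   and lumenal (lower) leaflet.
#' @param nominal_thickness nominal phosphate-to-phosphate distance in
#'   Angstrom, used for validation only.
#' @return an object of class \code{bilayer_spec}.
#' @export
bilayer_spec <- function(upper, lower, nominal_thickness = 34) {
  stopifnot(inherits(upper, "surface_spec"), inherits(lower, "surface_spec"))
  if (nominal_thickness <= 0) stop("nominal_thickness must be > 0")
  structure(list(upper = upper, lower = lower,
                 nominal_thickness = nominal_thickness),
            class = "bilayer_spec")
}

#' Lipid-trajectory specification for the synthetic generator
#'
#' Generated lipids carry one head (phosphate-analog) reference particle and
#' an acyl chain of \code{n_chain} carbons, each with \code{n_h} explicit
#' C-H unit vectors. C-H orientations are drawn from an exactly solvable
#' two-state mixture (perfectly aligned with the membrane normal vs
#' isotropic; perfectly perpendicular vs isotropic when \code{target_SCD} is
#' negative) so the expected deuterium order parameter equals
#' \code{target_SCD}. Flip-flops are instantaneous head translocations
#' across the midplane, drawn per lipid per frame with probability
#' \code{flip_rate}.
#'
#' @param n_lipids number of lipids.
#' @param n_frames number of frames.
#' @param dt time step between frames (arbitrary units, default 1).
#' @param target_SCD target deuterium order parameter in [-0.5, 1].
#' @param flip_rate expected flip-flop events per lipid per frame, in [0, 1].
#' @param hysteresis_gap size (Angstrom) of the midplane dead zone a head
#'   must clear for a flip to count; generated flips jump well past it.
#' @param box periodic box lengths (Angstrom), length-3 numeric.
#' @param leaflet_z height of the head plane above/below the midplane
#'   (Angstrom, default 17, i.e. a 34 A bilayer).
#' @param head_jitter_sd thermal jitter of head z positions (Angstrom).
#' @param n_chain chain carbons per lipid (default 16, palmitate-like;
#'   0 gives a heads-only trajectory for flip-flop studies).
#' @param n_h explicit hydrogens per chain carbon (default 2).
#' @param seed integer seed.
#' @return an object of class \code{trajectory_spec}.
#' @export
trajectory_spec <- function(n_lipids = 100, n_frames = 100, dt = 1,
                            target_SCD = 0.2, flip_rate = 0,
                            hysteresis_gap = 10, box = c(200, 200, 100),
                            leaflet_z = 17, head_jitter_sd = 1,
                            n_chain = 16, n_h = 2, seed = 1L) {
  if (n_lipids < 1 || n_frames < 1) stop("need at least one lipid and frame")
  if (target_SCD < -0.5 || target_SCD > 1)
    stop("target_SCD must lie in [-0.5, 1]")
  if (flip_rate < 0 || flip_rate > 1) stop("flip_rate must lie in [0, 1]")
  if (hysteresis_gap < 0) stop("hysteresis_gap must be >= 0")
  if (length(box) != 3 || any(box <= 0)) stop("box must be 3 positive lengths")
  if (n_chain < 0 || n_h < 1) stop("invalid chain geometry")
  structure(list(n_lipids = as.integer(n_lipids),
                 n_frames = as.integer(n_frames), dt = dt,
                 target_SCD = target_SCD, flip_rate = flip_rate,
                 hysteresis_gap = hysteresis_gap, box = box,
                 leaflet_z = leaflet_z, head_jitter_sd = head_jitter_sd,
                 n_chain = as.integer(n_chain), n_h = as.integer(n_h),
                 seed = as.integer(seed)),
            class = "trajectory_spec")
}

#' Evaluate the analytic surface of a surface_spec
#'
#' Noise-free heights of the generating surface at given lateral positions.
#' This is the ground truth the reconstruction pipeline is tested against.
#'
#' @param spec a \code{surface_spec}.
#' @param x,y lateral coordinates (Angstrom), recycled to a common length.
#' @return numeric vector of heights z (Angstrom).
#' @export
surface_height <- function(spec, x, y) {
  r2 <- x^2 + y^2
  z <- rep(spec$z0, length.out = max(length(x), length(y)))
  if (spec$kind == "sphere_cap") {
    z <- z + sqrt(spec$R^2 - r2) - spec$R
  } else if (spec$kind == "gaussian_bump") {
    z <- z + spec$A * exp(-r2 / (2 * spec$sigma^2))
  } else if (spec$kind == "microsome_patch") {
    z <- z + sqrt(spec$R_bg^2 - r2) - spec$R_bg +
      spec$A * exp(-r2 / (2 * spec$sigma^2))
  }
  z
}

#' Analytic mean curvature of a surface_spec
#'
#' Exact mean curvature of the generating surface, computed from closed-form
#' first and second derivatives of the height function. Serves as the
#' independent oracle for the finite-difference curvature maps. Sign
#' convention: surface normal toward +z, so a bulge toward +z has negative
#' mean curvature at its apex.
#'
#' @inheritParams surface_height
#' @return numeric vector of mean curvatures (1/Angstrom).
#' @export
surface_mean_curvature <- function(spec, x, y) {
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r2 <- x^2 + y^2
  zx <- zy <- zxx <- zyy <- zxy <- numeric(n)
  add_sphere <- function(R) {
    s <- sqrt(R^2 - r2)
    zx <<- zx - x / s
    zy <<- zy - y / s
    zxx <<- zxx - 1 / s - x^2 / s^3
    zyy <<- zyy - 1 / s - y^2 / s^3
    zxy <<- zxy - x * y / s^3
  }
  add_bump <- function(A, sigma) {
    g <- A * exp(-r2 / (2 * sigma^2))
    zx <<- zx - x * g / sigma^2
    zy <<- zy - y * g / sigma^2
    zxx <<- zxx + g * (x^2 / sigma^4 - 1 / sigma^2)
    zyy <<- zyy + g * (y^2 / sigma^4 - 1 / sigma^2)
    zxy <<- zxy + g * x * y / sigma^4
  }
  if (spec$kind == "sphere_cap") add_sphere(spec$R)
  if (spec$kind == "gaussian_bump") add_bump(spec$A, spec$sigma)
  if (spec$kind == "microsome_patch") {
    add_sphere(spec$R_bg)
    add_bump(spec$A, spec$sigma)
  }
  ((1 + zx^2) * zyy - 2 * zx * zy * zxy + (1 + zy^2) * zxx) /
    (2 * (1 + zx^2 + zy^2)^1.5)
}
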