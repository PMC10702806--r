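#' Sample a scattered point cloud from an analytic leaflet surface
#'
#' Lateral positions are drawn uniformly at random over the box (mimicking
#' the irregular voxel positions of a segmentation, which stresses the
#' scattered interpolation downstream); heights are the analytic surface
#' plus additive Gaussian noise. Deterministic given \code{spec$seed}.
#'
#' @param spec a \code{\link{surface_spec}}.
#' @param leaflet label for the returned cloud.
#' @return a \code{\link{leaflet_cloud}}.
#' @export
gen_surface_cloud <- function(spec, leaflet = "upper") {
  stopifnot(inherits(spec, "surface_spec"))
  n <- max(3L, as.integer(round(spec$density * spec$extent^2)))
  half <- spec$extent / 2
  set.seed(spec$seed)
  x <- runif(n, -half, half)
  y <- runif(n, -half, half)
  z <- surface_height(spec, x, y)
  if (spec$noise_sd > 0) z <- z + rnorm(n, sd = spec$noise_sd)
  leaflet_cloud(cbind(x, y, z), leaflet = leaflet,
                provenance = paste0("synthetic:", spec$kind))
}

#' Generate a lensed bilayer as two leaflet point clouds
#'
#' The two leaflets of \code{spec} are sampled independently (different
#' derived seeds). By construction the lumenal-analog (lower) leaflet can
#' carry a larger bump than the upper one, so the membrane thins where it
#' bulges: thickness = upper - lower is reduced at the bump center by the
#' difference of the bump amplitudes.
#'
#' @param spec a \code{\link{bilayer_spec}}.
#' @return list with elements \code{upper} and \code{lower}, both
#'   \code{\link{leaflet_cloud}}s.
#' @export
gen_lensed_bilayer <- function(spec) {
  stopifnot(inherits(spec, "bilayer_spec"))
  up <- gen_surface_cloud(spec$upper, leaflet = "upper")
  lo_spec <- spec$lower
  lo_spec$seed <- lo_spec$seed + 104729L  # decorrelate the two leaflets
  lo <- gen_surface_cloud(lo_spec, leaflet = "lower")
  # noise-free analytic separation must stay positive everywhere sampled
  probe <- seq(-spec$upper$extent / 2, spec$upper$extent / 2, length.out = 201)
  pr <- expand.grid(x = probe, y = probe)
  sep <- surface_height(spec$upper, pr$x, pr$y) -
    surface_height(spec$lower, pr$x, pr$y)
  if (min(sep) <= 0)
    stop("geometry error: leaflet surfaces overlap (upper must stay above lower)")
  list(upper = up, lower = lo)
}

# two-state C-H orientation mixture hitting target_SCD in expectation:
# aligned (S = 1) vs isotropic (S = 0) for positive targets, perpendicular
# (S = -1/2) vs isotropic for negative ones.  Returns n unit vectors (n x 3).
draw_ch_vectors <- function(n, target_SCD) {
  if (target_SCD >= 0) {
    p <- target_SCD
    state_vec <- c(0, 0, 1)
    perp <- FALSE
  } else {
    p <- -2 * target_SCD
    perp <- TRUE
  }
  in_state <- runif(n) < p
  v <- matrix(0, n, 3)
  n_iso <- sum(!in_state)
  if (n_iso > 0) {  # uniform on the sphere
    u <- runif(n_iso, -1, 1)
    phi <- runif(n_iso, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    v[!in_state, ] <- cbind(s * cos(phi), s * sin(phi), u)
  }
  n_st <- sum(in_state)
  if (n_st > 0) {
    if (perp) {  # uniform in the membrane plane
      phi <- runif(n_st, 0, 2 * pi)
      v[in_state, ] <- cbind(cos(phi), sin(phi), 0)
    } else {
      v[in_state, ] <- matrix(c(0, 0, 1), n_st, 3, byrow = TRUE)
    }
  }
  v
}

#' Generate a synthetic lipid trajectory with known ground truth
#'
#' Each lipid carries a head reference particle and (optionally) an acyl
#' chain of \code{n_chain} carbons with \code{n_h} explicit hydrogens each.
#' C-H unit vectors are redrawn every frame from the two-state mixture of
#' \code{\link{trajectory_spec}}, so the expected deuterium order parameter
#' equals \code{target_SCD}. Flip-flop events are drawn per lipid per frame
#' with probability \code{flip_rate} and realized as instantaneous head
#' translocations across the midplane (no transit frames), giving the
#' detector unambiguous ground truth. The true event log is returned
#' alongside the trajectory.
#'
#' @param spec a \code{\link{trajectory_spec}}.
#' @return list with elements \code{traj} (a
#'   \code{\link{lipid_trajectory}}) and \code{truth} (an
#'   \code{\link{event_log}}).
#' @export
gen_lipid_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  nl <- spec$n_lipids; nf <- spec$n_frames
  nc <- spec$n_chain; nh <- spec$n_h
  apl <- 1L + nc * (1L + nh)            # atoms per lipid
  na <- nl * apl
  ch_bond <- 1.09                        # C-H bond length, A
  c_step <- 1.27                         # per-carbon drop along the normal, A

  # fixed lateral positions (lipids do not diffuse; lateral dynamics are not
  # part of the ground truth the downstream analyses need)
  lx <- runif(nl, 0, spec$box[1])
  ly <- runif(nl, 0, spec$box[2])
  leaflet0 <- rep(c(1, -1), length.out = nl)    # +1 upper, -1 lower

  # flip schedule: per lipid per frame Bernoulli(flip_rate); frame f event
  # means the head has switched sides between frame f-1 and f
  events <- NULL
  side <- matrix(rep(leaflet0, nf), nl, nf)
  if (spec$flip_rate > 0 && nf > 1) {
    flips <- matrix(runif(nl * (nf - 1)) < spec$flip_rate, nl, nf - 1)
    for (l in seq_len(nl)) {
      s <- leaflet0[l]
      for (f in seq_len(nf - 1L)) {
        if (flips[l, f]) {
          s <- -s
          events <- rbind(events,
                          data.frame(lipid = l, frame = f + 1L,
                                     direction = if (s > 0) "up" else "down",
                                     x = lx[l], y = ly[l]))
        }
        side[l, f + 1L] <- s
      }
    }
  }
  if (is.null(events))
    events <- data.frame(lipid = integer(), frame = integer(),
                         direction = character(),
                         x = numeric(), y = numeric())

  atoms <- data.frame(
    lipid = rep(seq_len(nl), each = apl),
    role = rep(c("head", rep(c("C", rep("H", nh)), nc)), nl),
    carbon = rep(c(NA_integer_,
                   rep(seq_len(nc), each = 1L + nh)[seq_len(nc * (1L + nh))]),
                 nl),
    stringsAsFactors = FALSE)
  atoms$name <- ifelse(atoms$role == "head", "PO4",
                       paste0(atoms$role, atoms$carbon))
  head_idx <- which(atoms$role == "head")
  c_idx <- which(atoms$role == "C")
  h_idx <- which(atoms$role == "H")
  # parent carbon row of each hydrogen (H rows follow their carbon)
  h_parent <- rep(c_idx, each = nh)

  coords <- array(NA_real_, c(na, 3, nf))
  for (f in seq_len(nf)) {
    s <- side[, f]
    head_z <- s * spec$leaflet_z +
      if (spec$head_jitter_sd > 0) rnorm(nl, sd = spec$head_jitter_sd) else 0
    fr <- matrix(0, na, 3)
    fr[head_idx, 1] <- lx; fr[head_idx, 2] <- ly
    fr[head_idx, 3] <- head_z
    if (nc > 0) {
      # chain carbons extend from the head toward the midplane
      ci <- rep(seq_len(nc), nl)                 # carbon index per C atom
      cl <- rep(seq_len(nl), each = nc)          # lipid of each C atom
      fr[c_idx, 1] <- lx[cl]
      fr[c_idx, 2] <- ly[cl]
      fr[c_idx, 3] <- head_z[cl] - s[cl] * c_step * ci
      ch <- draw_ch_vectors(length(h_idx), spec$target_SCD)
      fr[h_idx, ] <- fr[h_parent, ] + ch_bond * ch
    }
    coords[, , f] <- fr
  }
  traj <- lipid_trajectory(coords, atoms, box = spec$box,
                           time = spec$dt * seq_len(nf))
  list(traj = traj, truth = event_log(events, nf))
}

#' Deterministic toy structures for geometry and contact analyses
#'
#' Fixtures with exactly known geometry:
#' \describe{
#'   \item{single_atom}{one atom of radius \code{r} at the origin.}
#'   \item{two_helices}{two ideal alpha-helices (rise 1.5 A/residue, 100
#'     degrees/residue, C-alpha radius 2.3 A) with vertical axes separated
#'     by \code{separation} along x; chains A and B.}
#'   \item{hbond_pair}{a collinear donor-H-acceptor triple: N at the origin,
#'     H on the +x axis at NH bond length, O at \code{d_DA} along +x.}
#'   \item{sphere_pair}{two atoms of radius \code{r} at distance \code{d}
#'     along x.}
#' }
#'
#' @param kind fixture kind.
#' @param r atom radius (Angstrom).
#' @param separation helix axis separation (Angstrom).
#' @param n_res residues per helix.
#' @param d_DA donor-acceptor distance (Angstrom).
#' @param d sphere-pair center distance (Angstrom).
#' @return an \code{\link{atom_model}}.
#' @export
gen_toy_structure <- function(kind = c("single_atom", "two_helices",
                                       "hbond_pair", "sphere_pair"),
                              r = 1.9, separation = 12, n_res = 20,
                              d_DA = 2.9, d = 3.0) {
  kind <- match.arg(kind)
  if (kind == "single_atom") {
    df <- data.frame(element = "C", name = "CA", resid = 1L, resname = "ALA",
                     chain = "A", x = 0, y = 0, z = 0, radius = r)
  } else if (kind == "two_helices") {
    helix <- function(x0, chain) {
      i <- seq_len(n_res) - 1L
      ang <- i * 100 * pi / 180
      data.frame(element = "C", name = "CA", resid = i + 1L, resname = "ALA",
                 chain = chain,
                 x = x0 + 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i)
    }
    df <- rbind(helix(-separation / 2, "A"), helix(separation / 2, "B"))
  } else if (kind == "hbond_pair") {
    df <- data.frame(
      element = c("N", "H", "O"), name = c("N", "H", "O"),
      resid = c(1L, 1L, 2L), resname = c("ARG", "ARG", "GLU"),
      chain = c("A", "A", "B"),
      x = c(0, 1.0, d_DA), y = 0, z = 0)
  } else {
    df <- data.frame(element = "C", name = c("C1", "C2"),
                     resid = c(1L, 2L), resname = "UNK",
                     chain = c("A", "B"),
                     x = c(0, d), y = 0, z = 0, radius = r)
  }
  atom_model(df)
}
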