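head_z_matrix <- function(traj) {
  heads <- which(traj$atoms$role == "head")
  if (length(heads) == 0)
    stop("selection error: no head particles in trajectory")
  z <- traj$coords[heads, 3, , drop = FALSE]
  dim(z) <- c(length(heads), n_frames(traj))
  list(z = z, lipid = traj$atoms$lipid[heads])
}

#' Leaflet assignment with hysteresis
#'
#' Labels each lipid per frame by the sign of (head z - midplane), with a
#' dead zone: a lipid's label only changes once its head crosses beyond
#' midplane +/- hysteresis_gap / 2, which suppresses spurious flips from
#' thermal jitter near the midplane. The midplane is recomputed per frame as
#' the mean head z (robust to slow drift) unless given.
#'
#' @param traj a \code{\link{lipid_trajectory}} with head particles.
#' @param hysteresis_gap dead-zone width (Angstrom), default 10
#'   (about half a leaflet).
#' @param midplane fixed midplane height, or NULL for the per-frame mean.
#' @return integer matrix (n_lipids x n_frames) of labels, +1 upper /
#'   -1 lower, with lipid ids as row names.
#' @export
assign_leaflets <- function(traj, hysteresis_gap = 10, midplane = NULL) {
  hz <- head_z_matrix(traj)
  nf <- ncol(hz$z)
  mid <- if (is.null(midplane)) colMeans(hz$z) else rep(midplane, nf)
  dz <- sweep(hz$z, 2, mid)
  gap <- hysteresis_gap / 2
  lab <- matrix(0L, nrow(dz), nf)
  # initial label: plain sign at the first frame (ties go to lower)
  lab[, 1] <- ifelse(dz[, 1] > 0, 1L, -1L)
  if (nf > 1) for (f in 2:nf) {
    prev <- lab[, f - 1L]
    flip_up <- prev < 0 & dz[, f] > gap
    flip_dn <- prev > 0 & dz[, f] < -gap
    lab[, f] <- prev
    lab[flip_up, f] <- 1L
    lab[flip_dn, f] <- -1L
  }
  rownames(lab) <- hz$lipid
  lab
}

#' Detect lipid flip-flop events
#'
#' One event per completed leaflet-label change (see
#' \code{\link{assign_leaflets}}), with the lipid id, frame of completion,
#' direction, and the head's lateral position at that frame (enabling
#' spatial attribution of flip-flop hot spots). The cumulative event curve
#' over time is carried by the returned \code{\link{event_log}}.
#'
#' @inheritParams assign_leaflets
#' @return an \code{\link{event_log}}.
#' @export
detect_flipflops <- function(traj, hysteresis_gap = 10, midplane = NULL) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  lab <- assign_leaflets(traj, hysteresis_gap, midplane)
  heads <- which(traj$atoms$role == "head")
  chg <- which(lab[, -1, drop = FALSE] != lab[, -ncol(lab), drop = FALSE],
               arr.ind = TRUE)
  if (nrow(chg) == 0) {
    ev <- data.frame(lipid = integer(), frame = integer(),
                     direction = character(), x = numeric(), y = numeric())
  } else {
    l <- chg[, 1]; f <- chg[, 2] + 1L
    hx <- traj$coords[heads, 1, , drop = FALSE]
    hy <- traj$coords[heads, 2, , drop = FALSE]
    dim(hx) <- dim(hy) <- c(length(heads), n_frames(traj))
    ev <- data.frame(
      lipid = traj$atoms$lipid[heads][l],
      frame = f,
      direction = ifelse(lab[cbind(l, f)] > 0, "up", "down"),
      x = hx[cbind(l, f)],
      y = hy[cbind(l, f)])
  }
  event_log(ev, n_frames(traj))
}

#' Distance between the centers of geometry of two atom selections
#'
#' Per frame, the Euclidean distance between the unweighted centroids of two
#' selections; used for the lateral-gate helix-pair (TM2-TM7) distance.
#'
#' @param traj a \code{\link{lipid_trajectory}}.
#' @param sel_a,sel_b integer atom indices (e.g. from
#'   \code{\link{select_atoms}}); must be non-empty and disjoint.
#' @return numeric vector, one distance (Angstrom) per frame.
#' @export
gate_distance <- function(traj, sel_a, sel_b) {
  if (length(sel_a) == 0 || length(sel_b) == 0)
    stop("selection error: empty selection")
  if (length(intersect(sel_a, sel_b)) > 0)
    stop("selection error: selections overlap")
  na <- dim(traj$coords)[1]
  if (max(sel_a, sel_b) > na)
    stop("selection error: atom index beyond trajectory size")
  cog <- function(sel) apply(traj$coords[sel, , , drop = FALSE], c(2, 3), mean)
  d <- cog(sel_a) - cog(sel_b)                       # 3 x n_frames
  sqrt(colSums(d^2))
}

#' Kabsch superposition
#'
#' Optimal proper rotation and translation minimizing the RMSD between two
#' coordinate sets, via SVD of the covariance matrix with the determinant
#' sign corrected (no reflections).
#'
#' @param mobile,ref N x 3 coordinate matrices.
#' @return list with \code{R} (3 x 3 rotation), \code{t} (translation such
#'   that \code{mobile \%*\% R + t} superposes onto \code{ref}) and
#'   \code{rmsd}.
#' @export
kabsch <- function(mobile, ref) {
  mobile <- as.matrix(mobile); ref <- as.matrix(ref)
  if (!all(dim(mobile) == dim(ref)))
    stop("selection error: atom counts differ between mobile and reference")
  mc <- colMeans(mobile); rc <- colMeans(ref)
  A <- sweep(mobile, 2, mc); B <- sweep(ref, 2, rc)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- A %*% R
  list(R = R, t = rc - mc %*% R,
       rmsd = sqrt(mean(rowSums((fitted - B)^2))))
}

#' Superposition RMSD time series
#'
#' Per frame, superposes the selected atoms onto the reference by the Kabsch
#' algorithm and reports the post-fit RMSD.
#'
#' @param traj a \code{\link{lipid_trajectory}}.
#' @param ref reference coordinates: N x 3 matrix (N = length of
#'   \code{selection}) or an \code{\link{atom_model}} with matching atom
#'   count.
#' @param selection integer atom indices into the trajectory (default all).
#' @return numeric vector of RMSD values (Angstrom), one per frame.
#' @export
superpose_rmsd <- function(traj, ref, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1])
  if (inherits(ref, "atom_model")) ref <- as.matrix(ref[, c("x", "y", "z")])
  ref <- as.matrix(ref)
  if (nrow(ref) != length(selection))
    stop("selection error: reference has ", nrow(ref),
         " atoms but selection has ", length(selection))
  vapply(seq_len(n_frames(traj)), function(f) {
    co <- traj$coords[selection, , f, drop = FALSE]
    dim(co) <- c(length(selection), 3)
    kabsch(co, ref)$rmsd
  }, 0)
}

#' Hydrogen-bond detection criteria
#'
#' @param d_DA_max maximum donor-acceptor heavy-atom distance (Angstrom,
#'   default 3.5).
#' @param angle_DHA_min minimum donor-hydrogen-acceptor angle (degrees,
#'   default 150); applied only when an explicit hydrogen is given.
#' @return an object of class \code{hbond_criteria}.
#' @export
hbond_criteria <- function(d_DA_max = 3.5, angle_DHA_min = 150) {
  if (d_DA_max <= 0) stop("d_DA_max must be > 0")
  if (angle_DHA_min < 0 || angle_DHA_min > 180)
    stop("angle_DHA_min must lie in [0, 180]")
  structure(list(d_DA_max = d_DA_max, angle_DHA_min = angle_DHA_min),
            class = "hbond_criteria")
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' For each donor/acceptor pair, a bond is present in a frame iff the
#' donor-acceptor distance is at most \code{d_DA_max} and, when the donor's
#' hydrogen is given, the D-H...A angle is at least \code{angle_DHA_min}.
#' Occupancy is the fraction of frames in which the bond is present.
#'
#' @param traj a \code{\link{lipid_trajectory}} (a static
#'   \code{\link{atom_model}} can be wrapped as a 1-frame trajectory with
#'   \code{\link{model_as_trajectory}}).
#' @param pairs data.frame with integer atom-index columns \code{donor},
#'   \code{acceptor} and optional \code{hydrogen} (NA where implicit).
#' @param crit an \code{\link{hbond_criteria}}.
#' @return \code{pairs} with an added \code{occupancy} column.
#' @export
hbond_occupancy <- function(traj, pairs, crit = hbond_criteria()) {
  if (nrow(pairs) == 0) stop("selection error: empty donor/acceptor set")
  nf <- n_frames(traj)
  occ <- numeric(nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    D <- traj$coords[pairs$donor[p], , , drop = FALSE]
    A <- traj$coords[pairs$acceptor[p], , , drop = FALSE]
    dim(D) <- c(3, nf); dim(A) <- c(3, nf)
    dDA <- sqrt(colSums((D - A)^2))
    present <- dDA <= crit$d_DA_max
    hcol <- pairs$hydrogen
    if (!is.null(hcol) && !is.na(hcol[p])) {
      H <- traj$coords[hcol[p], , , drop = FALSE]
      dim(H) <- c(3, nf)
      v1 <- D - H; v2 <- A - H
      cosang <- colSums(v1 * v2) /
        (sqrt(colSums(v1^2)) * sqrt(colSums(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      present <- present & ang >= crit$angle_DHA_min
    }
    occ[p] <- mean(present)
  }
  pairs$occupancy <- occ
  pairs
}

#' Wrap a static atom model as a one-frame trajectory
#'
#' @param model an \code{\link{atom_model}}.
#' @return a \code{\link{lipid_trajectory}} with one frame.
#' @export
model_as_trajectory <- function(model) {
  co <- array(as.matrix(model[, c("x", "y", "z")]), c(nrow(model), 3, 1))
  lipid_trajectory(co, as.data.frame(model), time = 1)
}
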