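test_that("leaflet assignment splits heads by midplane sign", {
  z <- matrix(rep(c(17, -17), 10), 20, 5)
  tr <- scripted_head_traj(z)
  lab <- assign_leaflets(tr, hysteresis_gap = 10)
  expect_equal(sum(lab[, 1] > 0), 10)
  expect_equal(sum(lab[, 1] < 0), 10)
  expect_true(all(lab == lab[, 1]))   # static heads never change label
})

test_that("oscillation inside the hysteresis dead zone never changes labels", {
  set.seed(40)
  # one lipid wobbling within +/- 1 A of the midplane, others anchoring it
  nf <- 200
  z <- rbind(runif(nf, -1, 1),
             matrix(rep(c(17, -17), each = nf), 2, nf, byrow = TRUE))
  tr <- scripted_head_traj(z, x = c(5, 10, 15), y = c(0, 0, 0))
  lab <- assign_leaflets(tr, hysteresis_gap = 10, midplane = 0)
  expect_true(all(lab[1, ] == lab[1, 1]))
  ev <- detect_flipflops(tr, hysteresis_gap = 10, midplane = 0)
  expect_equal(nrow(ev$events), 0)
})

test_that("labels match generator truth at every frame", {
  spec <- trajectory_spec(n_lipids = 40, n_frames = 300, flip_rate = 2e-3,
                          n_chain = 0, seed = 41)
  out <- gen_lipid_trajectory(spec)
  lab <- assign_leaflets(out$traj, hysteresis_gap = 10)
  # reconstruct the true side per frame from the event schedule
  truth <- matrix(rep(c(1L, -1L), length.out = 40), 40, 300)
  for (i in seq_len(nrow(out$truth$events))) {
    e <- out$truth$events[i, ]
    truth[e$lipid, e$frame:300] <- if (e$direction == "up") 1L else -1L
  }
  expect_equal(unname(lab), truth)
})

test_that("a single scripted crossing yields one event with correct metadata", {
  z <- rbind(c(17, 17, -17, -17),
             matrix(rep(c(17, -17), each = 4), 2, 4, byrow = TRUE))
  tr <- scripted_head_traj(z, x = c(1, 2, 3), y = c(9, 0, 0))
  ev <- detect_flipflops(tr, hysteresis_gap = 10, midplane = 0)
  expect_equal(nrow(ev$events), 1)
  expect_equal(ev$events$lipid, 1)
  expect_equal(ev$events$frame, 3)
  expect_equal(ev$events$direction, "down")
  expect_equal(ev$events$x, 1)
  expect_equal(ev$events$y, 9)
  expect_equal(ev$cumulative, c(0, 0, 1, 1))
})

test_that("detected events equal generator truth exactly on jump trajectories", {
  spec <- trajectory_spec(n_lipids = 200, n_frames = 2000,
                          flip_rate = 2.5e-4, n_chain = 0, seed = 11)
  out <- gen_lipid_trajectory(spec)
  ev <- detect_flipflops(out$traj, hysteresis_gap = 10)
  expect_equal(nrow(ev$events), nrow(out$truth$events))
  expect_equal(ev$events$lipid, out$truth$events$lipid)
  expect_equal(ev$events$frame, out$truth$events$frame)
  expect_equal(ev$events$direction, out$truth$events$direction)
  # bookkeeping identity: per-lipid label changes == per-lipid events
  lab <- assign_leaflets(out$traj, hysteresis_gap = 10)
  changes <- rowSums(lab[, -1, drop = FALSE] != lab[, -ncol(lab), drop = FALSE])
  counts <- table(factor(ev$events$lipid, levels = seq_len(200)))
  expect_equal(unname(changes), as.numeric(counts))
})

test_that("widening the hysteresis gap never increases the event count", {
  spec <- trajectory_spec(n_lipids = 60, n_frames = 500, flip_rate = 1e-3,
                          n_chain = 0, head_jitter_sd = 3, seed = 42)
  out <- gen_lipid_trajectory(spec)
  n_small <- nrow(detect_flipflops(out$traj, hysteresis_gap = 5)$events)
  n_mid <- nrow(detect_flipflops(out$traj, hysteresis_gap = 10)$events)
  n_large <- nrow(detect_flipflops(out$traj, hysteresis_gap = 20)$events)
  expect_gte(n_small, n_mid)
  expect_gte(n_mid, n_large)
})

test_that("no false positives at flip_rate = 0 over 20 seeds", {
  for (s in 1:20) {
    out <- gen_lipid_trajectory(
      trajectory_spec(n_lipids = 50, n_frames = 100, flip_rate = 0,
                      n_chain = 0, head_jitter_sd = 2, seed = 1000 + s))
    expect_equal(nrow(detect_flipflops(out$traj, 10)$events), 0)
  }
})

test_that("gate distance tracks helix centroids per frame", {
  hh <- gen_toy_structure("two_helices", separation = 12, n_res = 20)
  co1 <- as.matrix(hh[, c("x", "y", "z")])
  co2 <- co1
  co2[hh$chain == "B", 1] <- co2[hh$chain == "B", 1] + 3  # translate mid-run
  co <- array(c(co1, co1, co2), c(nrow(hh), 3, 3))
  tr <- lipid_trajectory(co, as.data.frame(hh), time = 1:3)
  sa <- select_atoms(tr$atoms, chain = "A")
  sb <- select_atoms(tr$atoms, chain = "B")
  d <- gate_distance(tr, sa, sb)
  expect_equal(d, c(12, 12, 15))
  # brute-force centroid oracle
  cog <- function(co, idx) colMeans(co[idx, ])
  expect_equal(d[1], sqrt(sum((cog(co1, sa) - cog(co1, sb))^2)),
               tolerance = 1e-12)
  expect_error(gate_distance(tr, sa, integer(0)), "selection error")
  expect_error(gate_distance(tr, sa, c(sb, sa[1])), "selection error")
})

test_that("Kabsch RMSD is zero for any proper rigid transform", {
  set.seed(43)
  ref <- matrix(rnorm(60), 20, 3)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(1.1), sin(1.1), 0, -sin(1.1), cos(1.1)), 3, 3)
  moved <- ref %*% (Rz %*% Rx) + matrix(c(5, -3, 12), 20, 3, byrow = TRUE)
  expect_lt(kabsch(moved, ref)$rmsd, 1e-9)
  expect_lt(kabsch(ref, ref)$rmsd, 1e-12)
  # trajectory wrapper
  co <- array(c(ref, moved), c(20, 3, 2))
  tr <- lipid_trajectory(co, data.frame(name = rep("CA", 20)), time = 1:2)
  r <- superpose_rmsd(tr, ref)
  expect_lt(max(r), 1e-9)
  expect_error(superpose_rmsd(tr, ref[1:10, ]), "selection error")
})

test_that("Kabsch agrees with the bio3d oracle and Gaussian displacement law", {
  set.seed(44)
  ref <- matrix(rnorm(300, sd = 5), 100, 3)
  sigma <- 0.8
  mob <- ref + rnorm(300, sd = sigma)
  ours <- kabsch(mob, ref)$rmsd
  b3d <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)), fit = TRUE)
  expect_equal(ours, b3d, tolerance = 1e-3)
  # E[RMSD^2] ~ 3 sigma^2 for small random displacements (fit absorbs ~6 dof)
  n <- 4000
  ref2 <- matrix(rnorm(3 * n, sd = 10), n, 3)
  mob2 <- ref2 + rnorm(3 * n, sd = sigma)
  r2 <- kabsch(mob2, ref2)$rmsd
  sem <- sigma * sqrt(3) / sqrt(2 * n)     # delta-method SE of the RMSD
  expect_lt(abs(r2 - sigma * sqrt(3)), 3 * sem)
})

test_that("hydrogen-bond occupancy follows distance and angle criteria", {
  hb <- gen_toy_structure("hbond_pair", d_DA = 2.9)
  xyz <- as.matrix(hb[, c("x", "y", "z")])
  # scripted 10-frame trajectory: bond present in exactly 3 frames
  co <- array(0, c(3, 3, 10))
  for (f in 1:10) {
    co[, , f] <- xyz
    if (f > 3) co[3, 1, f] <- 5  # pull the acceptor out of range
  }
  tr <- lipid_trajectory(co, as.data.frame(hb), time = 1:10)
  pairs <- data.frame(donor = 1L, acceptor = 3L, hydrogen = 2L)
  occ <- hbond_occupancy(tr, pairs)
  expect_equal(occ$occupancy, 0.30)
  # distance criterion alone when no hydrogen is given
  occ2 <- hbond_occupancy(tr, data.frame(donor = 1L, acceptor = 3L,
                                         hydrogen = NA_integer_))
  expect_equal(occ2$occupancy, 0.30)
  # far pair never bonds
  far <- hbond_occupancy(tr, data.frame(donor = 2L, acceptor = 3L,
                                        hydrogen = NA_integer_),
                         hbond_criteria(d_DA_max = 1.5))
  expect_equal(far$occupancy, 0.0)
  # angle criterion: bent geometry fails at 150 degrees
  bent <- hb
  bent$y[2] <- 1.0   # H off-axis: D-H...A angle ~ 90-120 degrees
  trb <- model_as_trajectory(atom_model(as.data.frame(bent)))
  occ3 <- hbond_occupancy(trb, pairs)
  expect_equal(occ3$occupancy, 0.0)
  expect_error(hbond_occupancy(tr, pairs[0, ]), "selection error")
})
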