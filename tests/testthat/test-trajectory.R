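rand_coords <- function(n, sd = 5) matrix(rnorm(n * 3, 0, sd), ncol = 3)

rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

test_that("Kabsch superposition honors the rigid-body identities", {
  set.seed(5)
  P <- rand_coords(10)
  s <- kabsch_superpose(P, P)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:20) {
    P <- rand_coords(8)
    R <- rand_rotation()
    Q <- P %*% t(R) + matrix(runif(3, -20, 20), 8, 3, byrow = TRUE)
    s <- kabsch_superpose(P, Q)
    expect_lt(s$rmsd, 1e-10)
    expect_equal(s$Qfit, P, tolerance = 1e-8)
    expect_equal(det(s$rotation), 1, tolerance = 1e-10)  # proper rotation
  }
})

test_that("Kabsch rejects degenerate inputs", {
  expect_error(kabsch_superpose(rand_coords(2), rand_coords(2)),
               "at least 3")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))  # collinear
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
  expect_error(kabsch_superpose(rand_coords(4), rand_coords(5)),
               "equal dimensions")
})

test_that("Kabsch RMSD matches a rotation-grid oracle on 4-point sets", {
  set.seed(17)
  for (i in 1:3) {
    P <- rand_coords(4, 3)
    Q <- rand_coords(4, 3)
    r_kabsch <- kabsch_superpose(P, Q)$rmsd
    r_grid <- oracle_grid_rmsd(P, Q, n_angle = 60)
    expect_lte(r_kabsch, r_grid + 1e-9)   # grid can never beat the optimum
    expect_lt(abs(r_kabsch - r_grid), 0.05 * max(r_grid, 1))
  }
})

test_that("RMSD is symmetric and superposition never hurts", {
  set.seed(23)
  for (i in 1:20) {
    P <- rand_coords(7)
    Q <- rand_coords(7)
    ab <- kabsch_superpose(P, Q)$rmsd
    ba <- kabsch_superpose(Q, P)$rmsd
    expect_equal(ab, ba, tolerance = 1e-10)
    raw <- sqrt(mean(rowSums((P - Q)^2)))
    expect_lte(ab, raw + 1e-12)
  }
})

test_that("Kabsch agrees with the bio3d reference implementation", {
  set.seed(31)
  for (i in 1:10) {
    P <- rand_coords(9)
    Q <- rand_coords(9)
    ours <- kabsch_superpose(P, Q)$rmsd
    theirs <- bio3d::rmsd(as.numeric(t(P)), as.numeric(t(Q)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-4)
  }
})

test_that("rmsd_series tracks frames against the reference", {
  const <- trajectory(replicate(5, rand_coords(6) * 0 + 1,
                                simplify = FALSE))
  rs <- rmsd_series(const)
  expect_equal(rs$rmsd_A, rep(0, 5))

  single <- trajectory(list(rand_coords(6)))
  expect_equal(rmsd_series(single)$rmsd_A, 0)
  expect_error(rmsd_series(single, reference = 2), "out of range")

  sim <- gen_trajectory(trajectory_sim_config(n_frames = 30,
                                              n_replicates = 1,
                                              n_atoms = 12, n_clusters = 2,
                                              jitter_sd = 0.1, seed = 2))
  rs2 <- rmsd_series(sim$traj, reference = 1)
  own <- rs2$rmsd_A[sim$truth$assignment == sim$truth$assignment[1]]
  other <- rs2$rmsd_A[sim$truth$assignment != sim$truth$assignment[1]]
  expect_lt(max(own), min(other))   # bimodal split by planted cluster
})

test_that("GROMOS clustering matches hand-built structure", {
  idx <- trajectory(replicate(3, rand_coords(5), simplify = FALSE))
  one <- gromos_cluster(trajectory(lapply(1:4, function(i)
    matrix(1:15, ncol = 3))), cutoff = 1)
  expect_equal(length(one$sizes), 1L)
  expect_equal(one$sizes, 4L)

  # hand-built distance structure: frames 1-3 mutual neighbors, 4-5
  # mutual neighbors, groups far apart
  m <- matrix(10, 5, 5)
  m[1:3, 1:3] <- 1; m[4:5, 4:5] <- 1
  diag(m) <- 0
  cl <- gromos_cluster(m, cutoff = 2.5)
  expect_equal(cl$assignment, c(1, 1, 1, 2, 2))
  expect_equal(cl$sizes, c(3L, 2L))
  expect_equal(cl$centroids[1], 1L)   # lowest index wins the tie

  expect_error(gromos_cluster(matrix(numeric(0), 0, 0)), "empty")
  expect_error(gromos_cluster(m, cutoff = -1), "positive")
})

test_that("GROMOS clusters are disjoint, exhaustive and centroid-tight", {
  sim <- gen_trajectory(trajectory_sim_config(n_frames = 20,
                                              n_replicates = 2,
                                              n_atoms = 15, n_clusters = 3,
                                              jitter_sd = 0.15, seed = 4))
  m <- pairwise_rmsd(sim$traj)
  cl <- gromos_cluster(m, cutoff = 2.5)
  expect_equal(sort(unique(cl$assignment)), seq_along(cl$sizes))
  expect_equal(sum(cl$sizes), nrow(m))
  expect_true(all(diff(cl$sizes) <= 0))
  for (k in seq_along(cl$sizes)) {
    members <- which(cl$assignment == k)
    expect_true(cl$centroids[k] %in% members)
    expect_true(all(m[cl$centroids[k], members] <= 2.5))
  }
})

test_that("GROMOS agrees with a brute-force oracle on random trajectories", {
  set.seed(77)
  for (i in 1:20) {
    traj <- trajectory(replicate(15, rand_coords(6, sd = 2),
                                 simplify = FALSE))
    m <- oracle_rmsd_matrix(traj)
    cutoff <- runif(1, 1, 4)
    ours <- gromos_cluster(m, cutoff)
    oracle <- oracle_gromos(m, cutoff)
    expect_equal(ours$assignment, oracle$assignment)
    expect_equal(ours$centroids, oracle$centroids)
    expect_equal(ours$sizes, oracle$sizes)
  }
})

test_that("planted two-cluster structure is recovered exactly", {
  sim <- gen_trajectory(trajectory_sim_config(n_frames = 50,
                                              n_replicates = 2,
                                              n_atoms = 20, n_clusters = 2,
                                              jitter_sd = 0.1, seed = 12))
  cl <- gromos_cluster(sim$traj, cutoff = 2.5)
  expect_equal(length(cl$sizes), 2L)
  tab <- table(sim$truth$assignment, cl$assignment)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("hbond occupancy applies the geometric criterion", {
  # build a 4-frame, 4-atom trajectory by hand: donor at origin, hydrogen
  # on +x, acceptor alternating between 2.9 A (bonded) and 10 A (not)
  coords <- array(0, dim = c(4, 4, 3))
  for (f in 1:4) {
    coords[f, 2, ] <- c(1, 0, 0)
    coords[f, 3, ] <- c(ifelse(f <= 2, 2.9, 10), 0, 0)
    coords[f, 4, ] <- c(0, 5, 0)
  }
  traj <- trajectory(coords)
  spec_on <- hbond_spec("A1", "A2", "A3")
  occ <- hbond_occupancy(traj, spec_on)
  expect_equal(occ$table$occupancy_pct, 50)
  expect_equal(occ$frames[[1]], 1:2)

  always <- hbond_occupancy(
    trajectory(coords[1:2, , , drop = FALSE]), spec_on)
  expect_equal(always$table$occupancy_pct, 100)

  never <- hbond_occupancy(traj, hbond_spec("A1", "A2", "A4"))
  expect_equal(never$table$occupancy_pct, 0)
  expect_equal(nrow(never$report), 0L)       # excluded from >20% report

  expect_error(hbond_occupancy(traj, hbond_spec("A1", "A2", "ZZ")),
               "unknown atom")
  expect_error(hbond_spec("a", "b", "c", angle_cutoff = 190), "angle")
  expect_error(hbond_spec("a", "b", "c", distance_cutoff = -1), "distance")
})

test_that("occupancy is invariant to frame reordering", {
  sim <- gen_trajectory(trajectory_sim_config(
    n_frames = 40, n_replicates = 1, n_atoms = 12, n_clusters = 1,
    planted_hbonds = list(list(occupancy = 0.4)), seed = 9))
  occ1 <- hbond_occupancy(sim$traj, sim$truth$hbond_specs)
  perm <- sample(n_frames(sim$traj))
  shuf <- trajectory(sim$traj$coords[perm, , , drop = FALSE],
                     atoms = sim$traj$atoms)
  occ2 <- hbond_occupancy(shuf, sim$truth$hbond_specs)
  expect_equal(occ1$table$occupancy_pct, occ2$table$occupancy_pct)
})

test_that("report keeps only bonds above threshold, sorted descending", {
  sim <- gen_trajectory(trajectory_sim_config(
    n_frames = 50, n_replicates = 2, n_atoms = 16, n_clusters = 1,
    planted_hbonds = list(list(occupancy = 0.5), list(occupancy = 0.05)),
    seed = 14))
  occ <- hbond_occupancy(sim$traj, sim$truth$hbond_specs)
  expect_equal(nrow(occ$report), 1L)
  expect_equal(occ$report$occupancy_pct, 50)
  expect_equal(occ$table$occupancy_pct, c(50, 5))
  expect_equal(ncol(occ$per_replicate), 2L)
})

test_that("trajectories round-trip through multi-model PDB and text", {
  sim <- gen_trajectory(trajectory_sim_config(n_frames = 3,
                                              n_replicates = 1,
                                              n_atoms = 5, n_clusters = 1,
                                              seed = 3))
  p <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(sim$traj, p)
  back <- read_trajectory_pdb(p)
  expect_equal(n_frames(back), 3)
  expect_equal(n_atoms(back), 5)
  expect_equal(back$coords, sim$traj$coords, tolerance = 1e-3)  # PDB 3dp

  txt <- tempfile(fileext = ".txt")
  write_frames_table(sim$traj, txt)
  back2 <- read_frames_table(txt)
  expect_equal(back2$coords, sim$traj$coords, tolerance = 1e-12)
})

test_that("trajectory constructor validates shape and replicates", {
  expect_error(trajectory(list(rand_coords(4), rand_coords(5))),
               "same atom count")
  expect_error(trajectory(replicate(4, rand_coords(4), simplify = FALSE),
                          replicate = c(2, 1, 1, 1)), "non-decreasing")
  tr <- trajectory(replicate(4, rand_coords(4), simplify = FALSE),
                   replicate = c(1, 1, 2, 2))
  expect_output(print(tr), "2 replicate")
})
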