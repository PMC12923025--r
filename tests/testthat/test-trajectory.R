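# Trajectory I/O, superposition, downsampling.

test_that("PDB + DCD export round-trips through load_trajectory", {
  sys <- random_geometric_system(7, seed = 9)
  traj <- simulate_langevin(sys, n_frames = 20, seed = 2)
  top <- tempfile(fileext = ".pdb")
  dcd <- tempfile(fileext = ".dcd")
  export_trajectory(traj, top, dcd)
  back <- load_trajectory(top, dcd)
  expect_equal(trajectory_frames(back), 20)
  expect_equal(trajectory_atoms(back), 7)
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3)  # float32 Angstrom
  expect_equal(back$atom_meta$resno, traj$atom_meta$resno)
})

test_that("degenerate exports and unsupported formats are rejected", {
  sys <- random_geometric_system(5, seed = 1)
  traj <- simulate_langevin(sys, n_frames = 3, seed = 1)
  expect_error(export_trajectory(traj, tempfile(fileext = ".pdb"),
                                 tempfile(fileext = ".xtc")),
               "supported")
  expect_error(load_trajectory(tempfile(fileext = ".pdb")), "not found")
  empty <- traj
  empty$coords <- traj$coords[0, , , drop = FALSE]
  expect_error(export_trajectory(structure(empty, class = "Trajectory"),
                                 tempfile(fileext = ".pdb"),
                                 tempfile(fileext = ".dcd")),
               "zero frames")
})

test_that("atom-count mismatch between topology and coordinates errors", {
  t10 <- simulate_langevin(random_geometric_system(10, seed = 3), 5, seed = 1)
  t12 <- simulate_langevin(random_geometric_system(12, seed = 3), 5, seed = 1)
  top10 <- tempfile(fileext = ".pdb")
  dcd12 <- tempfile(fileext = ".dcd")
  export_trajectory(t10, top10, tempfile(fileext = ".dcd"))
  export_trajectory(t12, tempfile(fileext = ".pdb"), dcd12)
  expect_error(load_trajectory(top10, dcd12), "mismatch")
})

test_that("PDB Angstrom coordinates are stored as nm", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, c(0, 10, 20), c(0, 0, 0), c(0, 0, 0)),
    "END"
  ), pdb)
  traj <- load_trajectory(pdb)
  expect_equal(traj$coords[1, , 1], c(0, 1, 2))  # 10 A -> 1 nm
})

test_that("GRO topology (nm units) loads directly", {
  gro <- tempfile(fileext = ".gro")
  writeLines(c(
    "toy system",
    "    3",
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1:3, "GLY", "CA", 1:3,
            c(0, 1, 2), c(0, 0, 0), c(0.5, 0.5, 0.5)),
    "   5.0   5.0   5.0"
  ), gro)
  traj <- load_trajectory(gro)
  expect_equal(trajectory_atoms(traj), 3)
  expect_equal(traj$coords[1, , 1], c(0, 1, 2))
})

test_that("superposition removes arbitrary rigid motions", {
  traj <- rigid_motion_trajectory(n_frames = 10, n_atoms = 6)
  fitted <- superpose(traj, reference_frame = 1,
                      selection = seq_len(6))
  for (f in 1:10) {
    rmsd <- sqrt(mean(rowSums((fitted$coords[f, , ] - fitted$coords[1, , ])^2)))
    expect_lt(rmsd, 1e-6)
  }
  # idempotence
  again <- superpose(fitted, reference_frame = 1, selection = seq_len(6))
  expect_lt(max(abs(again$coords - fitted$coords)), 1e-9)
  # input not modified
  expect_false(isTRUE(all.equal(traj$coords, fitted$coords)))
})

test_that("Kabsch fit is at least as good as a quaternion-grid search", {
  with_seed(5, {
    base <- matrix(stats::runif(15), 5, 3)
    moved <- sweep(base %*% random_rotation(), 2, c(1, -2, 0.5), `+`) +
      matrix(stats::rnorm(15, sd = 0.02), 5, 3)
  })
  coords <- array(NA_real_, c(2, 5, 3))
  coords[1, , ] <- base
  coords[2, , ] <- moved
  fitted <- superpose(trajectory(coords, ca_meta(5)), 1, selection = 1:5)
  kabsch_rmsd <- sqrt(mean(rowSums((fitted$coords[2, , ] - base)^2)))

  # brute force over a quaternion grid (~2 degree resolution around axes)
  best <- Inf
  b0 <- sweep(base, 2, colMeans(base))
  m0 <- sweep(moved, 2, colMeans(moved))
  angles <- seq(0, 2 * pi, by = 2 * pi / 180)
  with_seed(42, axes <- matrix(stats::rnorm(3 * 200), 200, 3))
  axes <- axes / sqrt(rowSums(axes^2))
  for (i in seq_len(nrow(axes))) {
    for (th in angles) {
      q <- c(cos(th / 2), sin(th / 2) * axes[i, ])
      R <- quat_to_rot(q)
      best <- min(best, sqrt(mean(rowSums((m0 %*% R - b0)^2))))
    }
  }
  expect_lte(kabsch_rmsd, best + 1e-6)
})

test_that("uniform downsampling follows the even-spacing index rule", {
  coords <- array(stats::rnorm(11 * 3 * 3), c(11, 3, 3))
  traj <- trajectory(coords, ca_meta(3), times = 0:10)
  down <- downsample_uniform(traj, 5)
  expect_equal(down$times, c(0, 2, 5, 7, 10))
  expect_identical(downsample_uniform(traj, 11), traj)
  expect_identical(downsample_uniform(traj, 20), traj)
})

test_that("downsampling ~300k frames to 5000 gives stride-60 spacing", {
  coords <- array(0, c(300000, 1, 3))
  coords[, 1, 1] <- seq_len(300000)
  traj <- trajectory(coords, ca_meta(1), times = seq_len(300000) - 1)
  down <- downsample_uniform(traj, 5000)
  expect_equal(trajectory_frames(down), 5000)
  strides <- diff(down$times)
  expect_true(all(strides %in% c(60, 61)))
  expect_equal(down$times[1], 0)
})
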