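# Structural observables: RMSD, RMSF, contacts, H-bonds, Rg, SASA, PCA, FEL.

test_that("RMSD is zero for identical frames and rigid copies", {
  traj <- static_trajectory(matrix(stats::runif(18), 6, 3), n_frames = 5)
  expect_equal(rmsd_series(traj), rep(0, 5), tolerance = 1e-12)
  rigid <- rigid_motion_trajectory(n_frames = 6, n_atoms = 5)
  expect_true(all(rmsd_series(rigid, selection = 1:5) < 1e-6))
})

test_that("RMSD equals brute-force minimization on a distorted toy", {
  with_seed(31, {
    base <- matrix(stats::runif(15), 5, 3)
    frame2 <- base + matrix(stats::rnorm(15, sd = 0.1), 5, 3)
  })
  coords <- array(NA_real_, c(2, 5, 3))
  coords[1, , ] <- base
  coords[2, , ] <- frame2
  traj <- trajectory(coords, ca_meta(5))
  got <- rmsd_series(traj, selection = 1:5)[2]

  obj <- function(par) {
    R <- quat_to_rot(c(cos(par[1] / 2), sin(par[1] / 2) *
                         par[2:4] / sqrt(sum(par[2:4]^2))))
    sqrt(mean(rowSums((sweep(frame2 %*% R, 2, par[5:7], `+`) - base)^2)))
  }
  best <- Inf
  for (i in 1:20) {
    with_seed(i, start <- c(stats::runif(1, 0, pi), stats::rnorm(3), 0, 0, 0))
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    best <- min(best, fit$value)
  }
  expect_equal(got, best, tolerance = 1e-4)
})

test_that("RMSF matches hand calculations", {
  traj <- static_trajectory(matrix(stats::runif(9), 3, 3), n_frames = 4)
  expect_equal(rmsf_profile(traj)$rmsf, rep(0, 3), tolerance = 1e-12)

  # one atom alternating between two points distance d apart -> RMSF d/2
  d <- 0.8
  coords <- array(0, c(6, 3, 3))
  coords[, 2, 1] <- 5  # spectators so superposition-free input is fine
  coords[, 3, 2] <- 5
  coords[c(2, 4, 6), 1, 1] <- d
  traj <- trajectory(coords, ca_meta(3))
  expect_equal(rmsf_profile(traj)$rmsf[1], d / 2, tolerance = 1e-12)
})

test_that("contact counting obeys the 0.45 nm heavy-atom criterion", {
  xyz <- rbind(c(0, 0, 0), c(0.40, 0, 0))
  traj <- static_trajectory(xyz, n_frames = 1,
                            meta = ca_meta(2))
  expect_equal(count_contacts(traj), 1L)
  xyz2 <- rbind(c(0, 0, 0), c(0.50, 0, 0))
  expect_equal(count_contacts(static_trajectory(xyz2, 1, ca_meta(2))), 0L)
  # same-residue pairs are excluded
  meta <- ca_meta(2)
  meta$resno <- c(1L, 1L)
  expect_equal(count_contacts(static_trajectory(xyz, 1, meta)), 0L)
})

test_that("cell-list contact counts equal brute force on random frames", {
  for (seed in 1:20) {
    with_seed(seed, {
      xyz <- matrix(stats::runif(300, 0, 2.5), 100, 3)
      resno <- sample(1:40, 100, replace = TRUE)
    })
    expect_identical(
      allokit:::contact_count_frame(xyz, resno, 0.45),
      as.integer(allokit:::contact_count_brute(xyz, resno, 0.45))
    )
  }
})

test_that("hydrogen bonds follow the distance and angle criteria exactly", {
  build <- function(d_no, angle_deg) {
    # donor N at origin, H on x-axis, acceptor placed for given D-H-A angle
    nh <- 0.10
    h <- c(nh, 0, 0)
    theta <- (180 - angle_deg) * pi / 180
    ha <- d_no - nh  # collinear when angle = 180
    a <- h + (d_no - nh) * c(cos(theta), sin(theta), 0)
    xyz <- rbind(c(0, 0, 0), h, a)
    meta <- data.frame(elety = c("N", "H", "O"), resno = c(1L, 1L, 2L),
                       resid = "GLY", chain = "A",
                       element = c("N", "H", "O"),
                       heavy = c(TRUE, FALSE, TRUE))
    static_trajectory(xyz, 1, meta)
  }
  hit <- hydrogen_bonds(build(0.30, 180))[[1]]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 0.30, tolerance = 1e-9)
  expect_equal(nrow(hydrogen_bonds(build(0.30, 140))[[1]]), 0)
  expect_equal(nrow(hydrogen_bonds(build(0.36, 180))[[1]]), 0)
  expect_warning(hydrogen_bonds(static_trajectory(diag(3), 1, ca_meta(3))),
                 "no hydrogens")
})

test_that("radius of gyration has its closed forms", {
  one <- static_trajectory(matrix(c(1, 2, 3), 1, 3), 2)
  expect_equal(radius_of_gyration(one), c(0, 0), tolerance = 1e-12)
  d <- 0.6
  two <- static_trajectory(rbind(c(0, 0, 0), c(d, 0, 0)), 2)
  expect_equal(radius_of_gyration(two)[1], d / 2, tolerance = 1e-12)
  scaled <- two
  scaled$coords <- two$coords * 2
  expect_equal(radius_of_gyration(structure(scaled, class = "Trajectory"))[1],
               d, tolerance = 1e-12)
})

test_that("SASA matches the analytic sphere and occlusion limits", {
  iso <- sasa(matrix(0, 1, 3), radii = 0.17)
  expect_equal(iso$total, 4 * pi * (0.17 + 0.14)^2, tolerance = 0.02)
  # atom enclosed inside a much larger overlapping neighbor
  enc <- sasa(rbind(c(0, 0, 0), c(0.05, 0, 0)), radii = c(0.1, 1.0))
  expect_equal(enc$atom_area[1], 0)
  # occlusion is monotone in distance
  near <- sasa(rbind(c(0, 0, 0), c(0.3, 0, 0)), radii = c(0.17, 0.17))
  far <- sasa(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(0.17, 0.17))
  expect_lt(near$total, far$total)
})

test_that("essential dynamics satisfies its spectral identities", {
  traj <- simulate_langevin(random_geometric_system(6, seed = 8), 200, seed = 3)
  traj <- superpose(traj)
  ed <- essential_dynamics(traj)
  expect_equal(sum(ed$eigenvalues),
               sum(apply(ed$projections, 2, function(p) mean(p^2))),
               tolerance = 1e-8)
  # eigenvector orthonormality
  g <- crossprod(ed$eigenvectors)
  expect_lt(max(abs(g - diag(nrow(g)))), 1e-8)
  # sum of eigenvalues = trace of covariance = sum RMSF^2
  rmsf <- rmsf_profile(traj)$rmsf
  expect_equal(sum(ed$eigenvalues), sum(rmsf^2), tolerance = 1e-8)
  # full-basis reconstruction
  recon <- ed$projections %*% t(ed$eigenvectors)
  X <- t(vapply(seq_len(trajectory_frames(traj)), function(f) {
    as.numeric(t(traj$coords[f, , ]))
  }, numeric(18)))
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(recon - Xc)), 1e-8)
})

test_that("motion along a single axis loads entirely on PC1", {
  coords <- array(0, c(50, 3, 3))
  base <- matrix(stats::runif(9), 3, 3)
  for (f in 1:50) {
    coords[f, , ] <- base
    coords[f, 1, 1] <- base[1, 1] + sin(f / 3)
  }
  ed <- essential_dynamics(trajectory(coords, ca_meta(3)))
  expect_equal(ed$eigenvalues[1] / sum(ed$eigenvalues), 1, tolerance = 1e-10)
})

test_that("free-energy surfaces follow the Boltzmann closed forms", {
  # uniform occupancy: one frame per bin
  pts <- as.matrix(expand.grid(x = c(-0.75, -0.25, 0.25, 0.75),
                               y = c(-0.75, -0.25, 0.25, 0.75)))
  fel <- free_energy_surface(pts, bins = 4)
  expect_true(all(fel$free_energy == 0))
  expect_equal(sum(fel$counts), nrow(pts))

  # a bin with half the maximum occupancy sits at ln 2
  proj <- rbind(matrix(rep(c(-0.5, -0.5), 4), ncol = 2, byrow = TRUE),
                matrix(rep(c(0.5, 0.5), 2), ncol = 2, byrow = TRUE))
  fel2 <- free_energy_surface(proj, bins = 2)
  expect_equal(min(fel2$free_energy), 0)
  expect_equal(sort(fel2$free_energy[is.finite(fel2$free_energy)]),
               c(0, log(2)), tolerance = 1e-12)
  expect_true(all(is.infinite(fel2$free_energy[fel2$counts == 0])))
  # single-basin degenerate input is valid
  one <- free_energy_surface(matrix(0, 5, 2), bins = 2)
  expect_equal(sum(one$counts), 5)
  expect_equal(min(one$free_energy), 0)
})

test_that("porcupine export writes consistent vectors", {
  traj <- superpose(simulate_langevin(random_geometric_system(5, seed = 2),
                                      60, seed = 4))
  ed <- essential_dynamics(traj)
  out <- tempfile(fileext = ".pml")
  res <- porcupine_export(ed, component = 1, scale = 2, out_path = out)
  expect_true(file.exists(res$script))
  tab <- utils::read.delim(res$table)
  expect_equal(nrow(tab), 5)
  norms <- sqrt(tab$dx^2 + tab$dy^2 + tab$dz^2)
  loads <- sqrt(colSums(matrix(ed$eigenvectors[, 1]^2, nrow = 3)))
  ratio <- norms / (2 * loads)
  expect_lt(diff(range(ratio)), 1e-10)
  res0 <- porcupine_export(ed, component = 1, scale = 0,
                           out_path = tempfile(fileext = ".pml"))
  expect_true(all(utils::read.delim(res0$table)[, 2:4] == 0))
})

test_that("observables are invariant under a global rigid motion", {
  sys <- random_geometric_system(8, seed = 14)
  traj <- superpose(simulate_langevin(sys, 80, seed = 6))
  R <- with_seed(3, random_rotation())
  shift <- c(1, -0.5, 2)
  rot <- traj
  for (f in seq_len(80)) {
    rot$coords[f, , ] <- sweep(traj$coords[f, , ] %*% R, 2, shift, `+`)
  }
  rot <- structure(rot, class = "Trajectory")
  expect_equal(rmsf_profile(rot)$rmsf, rmsf_profile(traj)$rmsf,
               tolerance = 1e-8)
  expect_equal(radius_of_gyration(rot), radius_of_gyration(traj),
               tolerance = 1e-8)
  expect_identical(count_contacts(rot), count_contacts(traj))
  expect_equal(essential_dynamics(rot)$eigenvalues,
               essential_dynamics(traj)$eigenvalues, tolerance = 1e-8)
  # SASA quadrature points are fixed in space, so rotating the molecule is
  # only invariant up to the discretization of the sphere
  expect_equal(sasa(rot$coords[1, , ], elements = rot$atom_meta$element)$total,
               sasa(traj$coords[1, , ], elements = traj$atom_meta$element)$total,
               tolerance = 5e-3)
})
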