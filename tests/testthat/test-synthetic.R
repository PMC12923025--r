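# Planted spring-network simulator.

test_that("zero-temperature edgeless system stays at its initial coordinates", {
  sys <- planted_system(matrix(stats::runif(9), 3, 3), edges = NULL,
                        temperature = 0)
  traj <- simulate_langevin(sys, n_frames = 5, seed = 1, dynamics = "brownian")
  for (f in 1:5) {
    expect_equal(traj$coords[f, , ], sys$initial_coords, tolerance = 0)
  }
  # inertial integrator starts from rest, so it is static too
  traj2 <- simulate_langevin(sys, n_frames = 5, seed = 1)
  expect_equal(traj2$coords[5, , ], sys$initial_coords, tolerance = 1e-12)
})

test_that("same system and seed give bit-identical trajectories", {
  sys <- random_geometric_system(8, seed = 2)
  a <- simulate_langevin(sys, n_frames = 50, save_stride = 3, seed = 99)
  b <- simulate_langevin(sys, n_frames = 50, save_stride = 3, seed = 99)
  expect_identical(a$coords, b$coords)
  c <- simulate_langevin(sys, n_frames = 50, save_stride = 3, seed = 100)
  expect_false(identical(a$coords, c$coords))
})

test_that("overdamped relaxation at zero temperature is monotone in energy", {
  sys <- random_geometric_system(8, seed = 5, temperature = 0,
                                 spring_style = "distance",
                                 friction = 1, timestep = 0.002,
                                 spring_constant = 50)
  # detune rest lengths so the start is strained
  sys$rest_length <- sys$rest_length * 0.8
  traj <- simulate_langevin(sys, n_frames = 40, save_stride = 5, seed = 1,
                            dynamics = "brownian")
  energies <- vapply(seq_len(40), function(f) {
    spring_energy(sys, traj$coords[f, , ])
  }, 0)
  expect_true(all(diff(energies) <= 1e-10))
})

test_that("bond-length variance matches equipartition and a fine-timestep reference", {
  kT <- 1
  k <- 50
  sys <- two_node_bond(k = k, kT = kT)
  traj <- simulate_langevin(sys, n_frames = 50000, seed = 4,
                            dynamics = "brownian")
  bond <- sqrt(rowSums((traj$coords[, 1, ] - traj$coords[, 2, ])^2))
  expect_equal(stats::var(bond), kT / k, tolerance = 0.10)

  # independent reference: 10x smaller timestep, same physics
  fine <- two_node_bond(k = k, kT = kT, timestep = 0.0002)
  ref <- simulate_langevin(fine, n_frames = 30000, save_stride = 10, seed = 8,
                           dynamics = "brownian")
  bond_ref <- sqrt(rowSums((ref$coords[, 1, ] - ref$coords[, 2, ])^2))
  expect_equal(stats::var(bond), stats::var(bond_ref), tolerance = 0.15)
})

test_that("bond-length variance decreases with spring stiffness", {
  vars <- vapply(c(25, 50, 100), function(k) {
    traj <- simulate_langevin(two_node_bond(k = k), n_frames = 30000,
                              seed = 21, dynamics = "brownian")
    stats::var(sqrt(rowSums((traj$coords[, 1, ] - traj$coords[, 2, ])^2)))
  }, 0)
  expect_true(all(diff(vars) < 0))
})

test_that("identity perturbation leaves apo and bound systems identical", {
  sc <- make_scenario(12, core_region = 1:4,
                      peripheral_regions = list(P1 = 5:8),
                      stiffening_factor = 1, softening_factor = 1, seed = 3)
  expect_identical(sc$apo$edges, sc$bound$edges)
  expect_equal(sc$apo$spring_constant, sc$bound$spring_constant)
  expect_equal(sc$apo$initial_coords, sc$bound$initial_coords)
})

test_that("scenario construction plants exactly the declared perturbations", {
  sc <- make_scenario(15, core_region = 1:5,
                      peripheral_regions = list(P1 = 6:9),
                      relay_spec = rbind(c(1, 15)),
                      stiffening_factor = 4, softening_factor = 0.25,
                      seed = 7, edges_per_node = 2)
  new_edges <- setdiff(allokit:::edge_key(sc$bound$edges),
                       allokit:::edge_key(sc$apo$edges))
  expect_identical(new_edges, "1-15")
  in_core <- sc$apo$edges[, 1] %in% 1:5 & sc$apo$edges[, 2] %in% 1:5
  shared <- match(allokit:::edge_key(sc$apo$edges),
                  allokit:::edge_key(sc$bound$edges))
  expect_equal(sc$bound$spring_constant[shared[in_core]],
               4 * sc$apo$spring_constant[in_core])
  in_p1 <- sc$apo$edges[, 1] %in% 6:9 & sc$apo$edges[, 2] %in% 6:9
  expect_equal(sc$bound$spring_constant[shared[in_p1]],
               0.25 * sc$apo$spring_constant[in_p1])
  expect_true(15 %in% sc$relay_nodes)
})

test_that("a relay edge already present in the apo graph is rejected", {
  sc <- make_scenario(10, core_region = 1:3, seed = 1)
  existing <- sc$apo$edges[1, , drop = FALSE]
  expect_error(
    make_scenario(10, core_region = 1:3, relay_spec = existing, seed = 1),
    "already present"
  )
})

test_that("scenario ground truth serializes to JSON and back", {
  sc <- make_scenario(10, core_region = 1:3,
                      peripheral_regions = list(P1 = 4:6), seed = 2)
  path <- tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(truth$n_nodes, 10)
  expect_equal(nrow(truth$apo_edges), nrow(sc$apo$edges))
  expect_equal(truth$core_region, 1:3)
})
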