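# Shared fixture builders. Everything is generated in code; no data files.

with_seed <- allokit:::with_seed
canonical_edges <- allokit:::canonical_edges
random_geometric_system <- allokit:::random_geometric_system
spring_energy <- allokit:::spring_energy

# Two particles joined by one scalar-distance spring.
two_node_bond <- function(k = 50, kT = 1, r0 = 0.5, friction = 1,
                          timestep = 0.002) {
  planted_system(
    rbind(c(0, 0, 0), c(r0, 0, 0)),
    edges = rbind(c(1, 2)),
    spring_constant = k, rest_length = r0, temperature = kT,
    friction = friction, timestep = timestep, spring_style = "distance"
  )
}

# Deterministic toy trajectory: n_atoms atoms doing a rigid-body tour of
# random rotations/translations of an irregular base structure.
rigid_motion_trajectory <- function(n_frames = 8, n_atoms = 6, seed = 11) {
  with_seed(seed, {
    base <- matrix(stats::runif(n_atoms * 3), n_atoms, 3)
    coords <- array(NA_real_, c(n_frames, n_atoms, 3))
    coords[1, , ] <- base
    for (f in 2:n_frames) {
      coords[f, , ] <- sweep(base %*% random_rotation(), 2,
                             stats::runif(3, -2, 2), `+`)
    }
    trajectory(coords, ca_meta(n_atoms))
  })
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  quat_to_rot(q / sqrt(sum(q^2)))
}

ca_meta <- function(n) {
  data.frame(elety = "CA", resno = seq_len(n), resid = "GLY", chain = "A",
             element = "C", heavy = TRUE, stringsAsFactors = FALSE)
}

# Static trajectory: the same frame repeated.
static_trajectory <- function(xyz, n_frames = 4, meta = NULL) {
  xyz <- as.matrix(xyz)
  coords <- array(NA_real_, c(n_frames, nrow(xyz), 3))
  for (f in seq_len(n_frames)) coords[f, , ] <- xyz
  trajectory(coords, meta %||% ca_meta(nrow(xyz)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
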