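#' Planted spring-network system
#'
#' A `PlantedSystem` is a set of point particles connected by harmonic
#' springs along a known (planted) interaction graph, evolved by overdamped
#' Langevin dynamics. It stands in for a protein whose residue interaction
#' network is known by construction, so that graph-inference methods can be
#' validated against ground truth. Units: nm, ps, and energies in units of
#' kT at the reference temperature (so `temperature = 1` means thermal noise
#' of magnitude kT = 1).
#'
#' @param initial_coords `n x 3` matrix of initial positions (nm).
#' @param edges two-column matrix of unordered node pairs (1-based); self
#'   edges are rejected.
#' @param spring_constant per-edge stiffness, scalar or one value per edge
#'   (kT / nm^2); must be positive.
#' @param rest_length per-edge equilibrium distance (nm), scalar or one per
#'   edge; non-negative. Defaults to the initial inter-node distances.
#' @param friction damping coefficient (1/ps), positive.
#' @param temperature thermal-noise scale in units of kT (0 switches noise off).
#' @param timestep integration step (ps), positive.
#' @param mass particle mass (u-like units; only used by the inertial
#'   integrator).
#' @param spring_style `"displacement"` (default): vector springs
#'   `U = k/2 |(x_i - x_j) - (h_i - h_j)|^2` acting on displacements from
#'   the reference geometry `h`, the linearized coupling of protein elastic
#'   network models; forces are linear in the coordinates. `"distance"`:
#'   scalar springs `U = k/2 (d - r0)^2` on the inter-node distance.
#' @param reference_coords reference geometry `h` for displacement springs
#'   (defaults to `initial_coords`). A matrix of zeros gives
#'   zero-rest-length springs, the classical interacting-particle benchmark
#'   for relational inference.
#' @return An object of class `PlantedSystem`.
#' @export
planted_system <- function(initial_coords, edges,
                           spring_constant = 1,
                           rest_length = NULL,
                           friction = 0.002,
                           temperature = 1,
                           timestep = 0.005,
                           mass = 1,
                           spring_style = c("displacement", "distance"),
                           reference_coords = NULL) {
  spring_style <- match.arg(spring_style)
  coords <- as.matrix(initial_coords)
  assert(ncol(coords) == 3L && nrow(coords) >= 2L,
         "initial_coords must be an n x 3 matrix with n >= 2")
  # canonicalize edges while keeping per-edge attributes aligned
  e_raw <- if (is.null(edges) || length(edges) == 0L) {
    matrix(integer(0), ncol = 2L)
  } else {
    matrix(as.integer(edges), ncol = 2L)
  }
  swap <- e_raw[, 1L] > e_raw[, 2L]
  e_raw[swap, ] <- e_raw[swap, c(2L, 1L)]
  assert(all(e_raw[, 1L] != e_raw[, 2L]), "self-edges are not allowed")
  assert(!anyDuplicated(e_raw), "duplicate edges are not allowed")
  k_raw <- rep_len(as.numeric(spring_constant), nrow(e_raw))
  r0_raw <- if (is.null(rest_length)) {
    if (nrow(e_raw) > 0) {
      sqrt(rowSums((coords[e_raw[, 1], , drop = FALSE] -
                    coords[e_raw[, 2], , drop = FALSE])^2))
    } else {
      numeric(0)
    }
  } else {
    rep_len(as.numeric(rest_length), nrow(e_raw))
  }
  ord <- order(e_raw[, 1L], e_raw[, 2L])
  e <- e_raw[ord, , drop = FALSE]
  colnames(e) <- c("i", "j")
  k <- k_raw[ord]
  r0 <- r0_raw[ord]
  assert(nrow(e) == 0L || max(e) <= nrow(coords), "edge index out of range")
  assert(all(k > 0), "all spring constants must be positive")
  assert(all(r0 >= 0), "rest lengths must be non-negative")
  assert(friction > 0, "friction must be positive")
  assert(temperature >= 0, "temperature must be non-negative")
  assert(timestep > 0, "timestep must be positive")
  assert(mass > 0, "mass must be positive")
  ref <- reference_coords %||% coords
  assert(identical(dim(as.matrix(ref)), dim(coords)),
         "reference_coords must match initial_coords in shape")
  ref <- as.matrix(ref)
  rest_vec <- if (nrow(e) > 0) {
    ref[e[, 1], , drop = FALSE] - ref[e[, 2], , drop = FALSE]
  } else {
    matrix(0, 0, 3)
  }
  structure(
    list(n_nodes = nrow(coords), initial_coords = coords, edges = e,
         spring_constant = k, rest_length = r0, rest_vec = rest_vec,
         spring_style = spring_style, friction = friction,
         temperature = temperature, timestep = timestep, mass = mass),
    class = "PlantedSystem"
  )
}

#' @export
print.PlantedSystem <- function(x, ...) {
  cat(sprintf("<PlantedSystem> %d nodes, %d springs, kT = %g, dt = %g ps\n",
              x$n_nodes, nrow(x$edges), x$temperature, x$timestep))
  invisible(x)
}

# Total harmonic spring energy of one configuration (kT units).
spring_energy <- function(system, coords) {
  e <- system$edges
  if (nrow(e) == 0L) return(0)
  dvec <- coords[e[, 1], , drop = FALSE] - coords[e[, 2], , drop = FALSE]
  if (system$spring_style == "displacement") {
    sum(0.5 * system$spring_constant * rowSums((dvec - system$rest_vec)^2))
  } else {
    d <- sqrt(rowSums(dvec^2))
    sum(0.5 * system$spring_constant * (d - system$rest_length)^2)
  }
}

# Negative gradient of the spring potential at configuration x (n x 3).
spring_forces <- function(x, system, frame) {
  e <- system$edges
  f <- matrix(0, nrow(x), 3)
  if (nrow(e) == 0L) return(f)
  dvec <- x[e[, 1], , drop = FALSE] - x[e[, 2], , drop = FALSE]
  if (system$spring_style == "displacement") {
    fvec <- system$spring_constant * (dvec - system$rest_vec)
  } else {
    r0 <- system$rest_length
    d <- sqrt(rowSums(dvec^2))
    if (any(!is.finite(d)) || any(d < 1e-12 & r0 > 0)) {
      stopf("integration failure at frame %d: overlapping nodes", frame)
    }
    fvec <- dvec * (system$spring_constant * (d - r0) / pmax(d, 1e-12))
  }
  if (any(!is.finite(fvec))) {
    stopf("integration failure at frame %d: non-finite forces", frame)
  }
  grad <- rowsum(rbind(fvec, -fvec), c(e[, 1], e[, 2]), reorder = FALSE)
  f[as.integer(rownames(grad)), ] <- -grad
  f
}

#' Simulate Langevin dynamics on a planted system
#'
#' Two integrators are available. The default, `"langevin"`, is inertial
#' (underdamped) Langevin dynamics via the BAOAB splitting: smooth,
#' force-dominated motion with thermal noise entering through the friction
#' channel; at low friction, short-time dynamics are nearly deterministic
#' and carry the interaction structure strongly, which is what relational
#' inference consumes. `"brownian"` is the overdamped limit
#' `dx = -(dt/gamma) grad U + sqrt(2 kT dt / gamma) N(0,1)`: purely
#' diffusive, with monotone energy relaxation at zero temperature. Both
#' sample the same Boltzmann ensemble (equipartition: bond-length variance
#' kT/k for a harmonic bond).
#'
#' One pseudo-atom (named CA, one residue per node) is emitted per node;
#' frames are saved every `save_stride` integration steps, starting from
#' the initial configuration with zero initial velocities.
#'
#' @param system a [planted_system()].
#' @param n_frames number of saved frames (at least 2).
#' @param save_stride integration steps between saved frames (default 1).
#' @param seed integer seed; the trajectory is bit-reproducible given
#'   (system, n_frames, save_stride, seed, dynamics).
#' @param dynamics `"langevin"` (inertial BAOAB, default) or `"brownian"`
#'   (overdamped).
#' @return A [trajectory()] with `n_frames` frames.
#' @export
simulate_langevin <- function(system, n_frames, save_stride = 1L, seed = 1L,
                              dynamics = c("langevin", "brownian")) {
  assert(inherits(system, "PlantedSystem"), "system must be a PlantedSystem")
  assert(n_frames >= 2L, "n_frames must be at least 2")
  assert(save_stride >= 1L, "save_stride must be at least 1")
  dynamics <- match.arg(dynamics)
  n <- system$n_nodes
  e <- system$edges
  k <- system$spring_constant
  r0 <- system$rest_length
  dt <- system$timestep
  kT <- system$temperature
  x <- system$initial_coords
  out <- array(NA_real_, c(n_frames, n, 3))
  out[1, , ] <- x
  with_seed(seed, {
    if (dynamics == "brownian") {
      mob <- dt / system$friction
      noise_sd <- sqrt(2 * kT * dt / system$friction)
      for (f in 2:n_frames) {
        for (s in seq_len(save_stride)) {
          x <- x + mob * spring_forces(x, system, f)
          if (noise_sd > 0) {
            x <- x + matrix(stats::rnorm(n * 3L, sd = noise_sd), n, 3)
          }
          if (any(!is.finite(x))) {
            stopf("integration failure at frame %d: non-finite coordinates", f)
          }
        }
        out[f, , ] <- x
      }
    } else {
      m <- system$mass
      # Maxwell-Boltzmann initial velocities with the center-of-mass
      # component removed: production then runs as a thermally
      # initialized, weakly coupled (near-NVE) trajectory
      v <- matrix(stats::rnorm(n * 3L, sd = sqrt(kT / m)), n, 3)
      v <- sweep(v, 2, colMeans(v))
      c1 <- exp(-system$friction * dt)
      c2 <- sqrt(kT / m * (1 - c1^2))
      f_now <- spring_forces(x, system, 1L)
      for (f in 2:n_frames) {
        for (s in seq_len(save_stride)) {
          v <- v + (dt / 2) * f_now / m          # B
          x <- x + (dt / 2) * v                  # A
          v <- c1 * v                            # O
          if (c2 > 0) {
            v <- v + c2 * matrix(stats::rnorm(n * 3L), n, 3)
            # keep the system frame fixed: thermostat noise would
            # otherwise random-walk the centre of mass and net rotation
            v <- remove_net_motion(x, v)
          }
          x <- x + (dt / 2) * v                  # A
          f_now <- spring_forces(x, system, f)
          v <- v + (dt / 2) * f_now / m          # B
          if (any(!is.finite(x))) {
            stopf("integration failure at frame %d: non-finite coordinates", f)
          }
        }
        out[f, , ] <- x
      }
    }
  })
  meta <- data.frame(
    elety = "CA", resno = seq_len(n), resid = "GLY", chain = "A",
    element = "C", heavy = TRUE, stringsAsFactors = FALSE
  )
  times <- (seq_len(n_frames) - 1) * dt * save_stride
  trajectory(out, meta, times)
}

# Remove centre-of-mass velocity and net angular momentum (equal masses).
remove_net_motion <- function(x, v) {
  v <- sweep(v, 2, colMeans(v))
  com <- colMeans(x)
  r <- sweep(x, 2, com)
  L <- c(sum(r[, 2] * v[, 3] - r[, 3] * v[, 2]),
         sum(r[, 3] * v[, 1] - r[, 1] * v[, 3]),
         sum(r[, 1] * v[, 2] - r[, 2] * v[, 1]))
  r2 <- rowSums(r^2)
  inertia <- diag(sum(r2), 3) - crossprod(r)
  omega <- tryCatch(solve(inertia, L), error = function(e) c(0, 0, 0))
  v - cbind(omega[2] * r[, 3] - omega[3] * r[, 2],
            omega[3] * r[, 1] - omega[1] * r[, 3],
            omega[1] * r[, 2] - omega[2] * r[, 1])
}

# Random geometric graph over seeded coordinates. The connection radius is
# chosen per instance so that the edge count is edges_per_node * n (keeping
# the planted graph sparsity protein-contact-like and stable across seeds);
# disconnected components are stitched by their closest inter-component
# node pair so that the network is connected like a protein contact graph.
random_geometric_system <- function(n_nodes, seed, edges_per_node = 1.3,
                                    density = 1.0, ...) {
  with_seed(seed, {
    box <- (n_nodes / density)^(1 / 3) * 0.55
    coords <- matrix(stats::runif(n_nodes * 3, 0, box), n_nodes, 3)
    dm <- as.matrix(stats::dist(coords))
    n_edges <- min(round(edges_per_node * n_nodes), n_nodes * (n_nodes - 1) / 2)
    cutoff <- sort(dm[upper.tri(dm)])[n_edges]
    adj <- dm <= cutoff & upper.tri(dm)
    edges <- which(adj, arr.ind = TRUE)[, c(1, 2), drop = FALSE]
    # stitch components
    repeat {
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
      comp <- igraph::components(g)$membership
      if (length(unique(comp)) <= 1L) break
      a <- which(comp == comp[1])
      b <- which(comp != comp[1])
      sub <- dm[a, b, drop = FALSE]
      hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
      edges <- rbind(edges, c(a[hit[1]], b[hit[2]]))
    }
    planted_system(coords, edges, ...)
  })
}

#' Apo/bound scenario pair with planted perturbations
#'
#' Builds two [planted_system()] objects sharing node positions and a random
#' geometric interaction graph. The "bound" system emulates ligand binding:
#' springs internal to the core region are stiffened (rigidification),
#' springs internal to each peripheral region are softened (flexibilization),
#' and the relay edges in `relay_spec` are added as new springs present only
#' in the bound state.
#'
#' @param n_nodes number of particles.
#' @param core_region integer vector of core node indices.
#' @param peripheral_regions named list of integer vectors (peripheral node
#'   sets).
#' @param relay_spec two-column matrix (or NULL) of extra bound-only edges;
#'   an edge already present in the apo graph is rejected.
#' @param stiffening_factor factor (>= 1) applied to core-internal spring
#'   constants in the bound state.
#' @param softening_factor factor in (0, 1] applied to peripheral-internal
#'   spring constants in the bound state.
#' @param seed integer seed controlling the geometry and graph.
#' @param edges_per_node target edge density of the random geometric graph.
#' @param extra_edges optional edges added to the base (apo) topology on
#'   top of the random geometric graph, e.g. to densify a core region the
#'   way packed protein cores are densely connected.
#' @param ... further arguments passed to [planted_system()] (spring
#'   constant, temperature, friction, timestep).
#' @return An object of class `ScenarioPair` with fields `apo`, `bound`,
#'   `core_region`, `peripheral_regions`, `relay_nodes`, `relay_edges`.
#' @export
make_scenario <- function(n_nodes, core_region, peripheral_regions = list(),
                          relay_spec = NULL, stiffening_factor = 4,
                          softening_factor = 0.25, seed = 1L,
                          edges_per_node = 1.3, extra_edges = NULL, ...) {
  assert(stiffening_factor >= 1, "stiffening_factor must be >= 1")
  assert(softening_factor > 0 && softening_factor <= 1,
         "softening_factor must be in (0, 1]")
  regions <- c(list(core = as.integer(core_region)),
               lapply(peripheral_regions, as.integer))
  for (nm in names(regions)) {
    assert(all(regions[[nm]] >= 1L & regions[[nm]] <= n_nodes),
           "region '%s' has node indices outside [1, %d]", nm, n_nodes)
  }
  apo <- random_geometric_system(n_nodes, seed = seed,
                                 edges_per_node = edges_per_node, ...)
  if (!is.null(extra_edges)) {
    extra <- canonical_edges(extra_edges)
    extra <- extra[!(edge_key(extra) %in% edge_key(apo$edges)), , drop = FALSE]
    if (nrow(extra) > 0L) {
      apo <- planted_system(
        apo$initial_coords, rbind(apo$edges, extra),
        spring_constant = c(apo$spring_constant,
                            rep(stats::median(apo$spring_constant),
                                nrow(extra))),
        friction = apo$friction, temperature = apo$temperature,
        timestep = apo$timestep, mass = apo$mass,
        spring_style = apo$spring_style
      )
    }
  }

  k_bound <- apo$spring_constant
  in_set <- function(e, set) e[, 1] %in% set & e[, 2] %in% set
  core_mask <- in_set(apo$edges, regions$core)
  k_bound[core_mask] <- k_bound[core_mask] * stiffening_factor
  for (nm in names(peripheral_regions)) {
    mask <- in_set(apo$edges, regions[[nm]])
    k_bound[mask] <- k_bound[mask] * softening_factor
  }

  relay_edges <- canonical_edges(relay_spec)
  if (nrow(relay_edges) > 0L) {
    assert(max(relay_edges) <= n_nodes, "relay edge index out of range")
    clash <- edge_key(relay_edges) %in% edge_key(apo$edges)
    assert(!any(clash),
           "relay edge(s) already present in the apo graph: %s",
           paste(edge_key(relay_edges)[clash], collapse = ", "))
  }
  # relay springs get ordinary stiffness: an extra-stiff relay chain would
  # move quasi-rigidly and induce end-to-end correlations that masquerade
  # as a direct source-target interaction
  relay_k <- stats::median(apo$spring_constant)
  relay_r0 <- if (nrow(relay_edges) > 0) {
    sqrt(rowSums((apo$initial_coords[relay_edges[, 1], , drop = FALSE] -
                  apo$initial_coords[relay_edges[, 2], , drop = FALSE])^2))
  } else {
    numeric(0)
  }
  bound <- planted_system(
    apo$initial_coords,
    rbind(apo$edges, relay_edges),
    spring_constant = c(k_bound, rep(relay_k, nrow(relay_edges))),
    rest_length = c(apo$rest_length, relay_r0),
    friction = apo$friction, temperature = apo$temperature,
    timestep = apo$timestep
  )
  relay_nodes <- setdiff(unique(as.integer(relay_edges)), regions$core)
  structure(
    list(apo = apo, bound = bound,
         core_region = regions$core,
         peripheral_regions = regions[setdiff(names(regions), "core")],
         relay_nodes = relay_nodes, relay_edges = relay_edges),
    class = "ScenarioPair"
  )
}

#' @export
print.ScenarioPair <- function(x, ...) {
  cat(sprintf(
    "<ScenarioPair> %d nodes | apo %d springs, bound %d springs | %d relay edge(s)\n",
    x$apo$n_nodes, nrow(x$apo$edges), nrow(x$bound$edges), nrow(x$relay_edges)))
  invisible(x)
}

#' Serialize scenario ground truth to JSON
#'
#' Writes the planted edges, per-edge spring constants, region definitions,
#' relay edges and scenario factors so that downstream evaluations can be
#' scored against ground truth without the R objects.
#'
#' @param scenario a [make_scenario()] result.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_scenario_json <- function(scenario, path) {
  truth <- list(
    n_nodes = scenario$apo$n_nodes,
    apo_edges = unname(apply(scenario$apo$edges, 1, as.list)),
    bound_edges = unname(apply(scenario$bound$edges, 1, as.list)),
    apo_spring_constant = scenario$apo$spring_constant,
    bound_spring_constant = scenario$bound$spring_constant,
    core_region = scenario$core_region,
    peripheral_regions = scenario$peripheral_regions,
    relay_nodes = scenario$relay_nodes,
    relay_edges = unname(apply(scenario$relay_edges, 1, as.list))
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
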