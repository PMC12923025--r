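#' Configuration for a two-state comparison run
#'
#' Collects every input and threshold of the apo-vs-bound pipeline so that
#' a run is fully reproducible from its config. The config hash (over all
#' fields except the output directory) keys the on-disk cache.
#'
#' @param apo_trajectories,bound_trajectories lists of replicates, each a
#'   list with `topology` and `coords` file paths.
#' @param regions a [region_set()] or named list of residue-number vectors;
#'   the first region is the path source unless `source_region` says
#'   otherwise.
#' @param nri an [nri_config()].
#' @param source_region name of the region whose geometric-center residue
#'   is the path source.
#' @param path_source optional explicit source residue overriding the
#'   geometric center.
#' @param contact_cutoff heavy-atom contact cutoff (nm).
#' @param hbond_d_cut,hbond_angle_cut hydrogen-bond criteria (nm, degrees).
#' @param min_probability edge retention threshold for [build_graph()]
#'   (NULL = 1 / n_edge_types).
#' @param target_frames uniform downsampling target before NRI.
#' @param window,stride segmentation parameters for NRI.
#' @param fraction residue fraction for sparse sampling before NRI (1 =
#'   all residues; 0.5 emulates spatially uniform sampling of large
#'   proteins).
#' @param nri_align superpose trajectories before computing NRI features
#'   (default TRUE, the protocol for real MD data). Synthetic
#'   planted-graph runs set this to FALSE: the simulator already holds the
#'   global frame fixed, and superposition pins the selection centroid
#'   exactly, which creates a graph/complement information degeneracy for
#'   the latent edge types.
#' @param fel_bins free-energy-surface bins per axis.
#' @param temperature temperature (K) recorded with energy landscapes.
#' @param pockets optional path to a pocket residue-list file (see
#'   [read_pockets()]).
#' @param out_dir output directory.
#' @param profile free-form label ("ci" or "full-scale").
#' @return A list of class `run_config` with a `hash` field.
#' @export
run_config <- function(apo_trajectories, bound_trajectories, regions,
                       nri = nri_config(profile = "ci"),
                       source_region = NULL, path_source = NULL,
                       contact_cutoff = 0.45, hbond_d_cut = 0.35,
                       hbond_angle_cut = 150, min_probability = NULL,
                       target_frames = 5000L, window = 50L, stride = 100L,
                       fraction = 1.0, nri_align = TRUE, fel_bins = 32L,
                       temperature = 300, pockets = NULL,
                       out_dir = tempfile("allokit-run-"),
                       profile = "ci") {
  assert(length(apo_trajectories) >= 1L && length(bound_trajectories) >= 1L,
         "need at least one replicate per state")
  regions <- as_region_list(regions)
  assert(length(regions) >= 2L, "need at least two regions (source + target)")
  cfg <- list(
    apo_trajectories = apo_trajectories,
    bound_trajectories = bound_trajectories,
    regions = regions, nri = nri,
    source_region = source_region %||% names(regions)[1],
    path_source = path_source,
    contact_cutoff = contact_cutoff, hbond_d_cut = hbond_d_cut,
    hbond_angle_cut = hbond_angle_cut, min_probability = min_probability,
    target_frames = as.integer(target_frames), window = as.integer(window),
    stride = as.integer(stride), fraction = fraction,
    nri_align = isTRUE(nri_align), fel_bins = as.integer(fel_bins),
    temperature = temperature, pockets = pockets, profile = profile
  )
  cfg$hash <- rlang::hash(cfg)
  cfg$out_dir <- out_dir
  class(cfg) <- "run_config"
  cfg
}

#' Hash of a run configuration
#'
#' Every threshold, seed and input path participates; the output directory
#' does not.
#' @param config a [run_config()].
#' @return character scalar.
#' @export
config_hash <- function(config) config$hash

log_stage <- function(stage, expr) {
  t0 <- Sys.time()
  message(sprintf("[allokit] %s ...", stage))
  out <- tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
  message(sprintf("[allokit] %s done (%.1f s)", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

# Concatenate replicate trajectories frame-wise (shared topology).
concat_trajectories <- function(trajs) {
  if (length(trajs) == 1L) return(trajs[[1]])
  coords <- do.call(abind3, lapply(trajs, `[[`, "coords"))
  dt <- diff(trajs[[1]]$times)[1] %||% 1
  trajectory(coords, trajs[[1]]$atom_meta,
             times = (seq_len(dim(coords)[1]) - 1) * dt)
}

abind3 <- function(...) {
  arrays <- list(...)
  d <- dim(arrays[[1]])
  total <- sum(vapply(arrays, function(a) dim(a)[1], 0L))
  out <- array(NA_real_, c(total, d[2], d[3]))
  at <- 0L
  for (a in arrays) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

# Per-state observable block on superposed replicates.
state_observables <- function(trajs, config, state) {
  cat_traj <- concat_trajectories(trajs)
  has_h <- any(cat_traj$atom_meta$element == "H")
  hb_counts <- if (has_h) {
    lengths(lapply(hydrogen_bonds(cat_traj, config$hbond_d_cut,
                                  config$hbond_angle_cut),
                   function(df) df$donor))
  } else {
    NULL
  }
  ed <- essential_dynamics(cat_traj)
  list(
    state = state,
    rmsd = lapply(trajs, rmsd_series),
    rmsf = rmsf_profile(cat_traj, state = state),
    rg = radius_of_gyration(cat_traj),
    contacts = count_contacts(cat_traj, config$contact_cutoff),
    hbond_counts = hb_counts,
    sasa_total = sasa(cat_traj$coords[1, , ],
                      elements = cat_traj$atom_meta$element)$total,
    ed = ed,
    fel = free_energy_surface(ed$projections[, 1:2, drop = FALSE],
                              bins = config$fel_bins,
                              temperature = config$temperature),
    mean_ca = ca_coords(cat_traj)
  )
}

# Per-state NRI: downsample, (optionally) sparse-sample, segment, train one
# model per replicate, average into a consensus latent graph.
state_nri <- function(trajs, config, state) {
  fits <- lapply(seq_along(trajs), function(r) {
    traj <- downsample_uniform(trajs[[r]], config$target_frames)
    selection <- if (config$fraction < 1) {
      sparse_sample(traj, config$fraction, seed = config$nri$seed)
    } else {
      NULL
    }
    feats <- compute_features(traj, selection)
    cfg <- config$nri
    cfg$seed <- cfg$seed + r - 1L  # independent replicate seeds
    train_nri(feats, cfg, window = config$window, stride = config$stride,
              replicate_id = sprintf("%s-rep%d", state, r))
  })
  list(fits = fits, consensus = consensus_graph(lapply(fits, `[[`, "graph")))
}

#' Run the full apo-vs-bound comparison
#'
#' Executes the pipeline end to end: load and superpose every replicate;
#' per-replicate RMSD; RMSF, radius of gyration, contacts, hydrogen bonds,
#' SASA, essential dynamics and free-energy landscapes on the concatenated
#' replicates; downsampling, optional sparse residue sampling, windowing
#' and per-replicate NRI training with replicate averaging; directed
#' communication graphs, total edge weight, betweenness, cross-region
#' strengths, shortest paths from the source-region center to every other
#' region center; relay detection between states; and, when pockets are
#' supplied, pocket prioritization. A completed report is cached in
#' `out_dir` under the config hash and reused on re-runs with an identical
#' config.
#'
#' @param config a [run_config()].
#' @param use_cache reuse a cached report with the same config hash?
#' @return An object of class `ComparisonReport` (a list; see the fields in
#'   the source or the written `report.json`).
#' @export
run_comparison <- function(config, use_cache = TRUE) {
  assert(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cache_file <- file.path(config$out_dir,
                          sprintf("report-%s.rds", config$hash))
  if (use_cache && file.exists(cache_file)) {
    message("[allokit] cache hit: ", cache_file)
    report <- readRDS(cache_file)
    write_report(report, config)
    return(report)
  }
  paths <- list(apo = config$apo_trajectories, bound = config$bound_trajectories)
  for (state in names(paths)) {
    for (rep in paths[[state]]) {
      for (f in c(rep$topology, rep$coords)) {
        assert(file.exists(f), "missing %s-state input file: %s", state, f)
      }
    }
  }
  loaded <- log_stage("load", lapply(paths, function(reps) {
    lapply(reps, function(rep) load_trajectory(rep$topology, rep$coords))
  }))
  report <- compare_states(loaded$apo, loaded$bound, config)
  saveRDS(report, cache_file)
  write_report(report, config)
  report
}

# Core comparison on in-memory (loaded, unaligned) trajectories;
# run_comparison is the file-based wrapper. Observables always use
# superposed coordinates; NRI features follow config$nri_align.
compare_states <- function(apo_trajs, bound_trajs, config) {
  sup <- log_stage("superpose", list(
    apo = lapply(apo_trajs, superpose),
    bound = lapply(bound_trajs, superpose)
  ))
  obs <- log_stage("observables", list(
    apo = state_observables(sup$apo, config, "apo"),
    bound = state_observables(sup$bound, config, "bound")
  ))
  nri_in <- if (isTRUE(config$nri_align)) {
    sup
  } else {
    list(apo = apo_trajs, bound = bound_trajs)
  }
  nri <- log_stage("NRI training", list(
    apo = state_nri(nri_in$apo, config, "apo"),
    bound = state_nri(nri_in$bound, config, "bound")
  ))
  graphs <- lapply(nri, function(s) {
    build_graph(s$consensus, config$min_probability)
  })
  metrics <- lapply(graphs, function(g) {
    list(total_edge_weight = total_edge_weight(g),
         mean_betweenness = mean(graph_betweenness(g)))
  })
  cross <- lapply(nri, function(s) {
    cross_region_strength(s$consensus, config$regions)
  })

  regions <- config$regions
  mean_ca <- obs$apo$mean_ca
  rownames(mean_ca) <- sort(unique(apo_trajs[[1]]$atom_meta$resno))
  src_region <- config$source_region
  source_res <- config$path_source %||%
    region_center_residue(mean_ca, regions[[src_region]])
  targets <- setdiff(names(regions), src_region)
  paths <- lapply(graphs, function(g) {
    out <- lapply(targets, function(tr) {
      shortest_path(g, source_res, region_center_residue(mean_ca, regions[[tr]]))
    })
    names(out) <- targets
    out
  })
  relay_report <- detect_relays(paths$apo, paths$bound)

  delta_rmsf <- region_delta_rmsf(obs$apo$rmsf, obs$bound$rmsf, regions)

  pocket_rank <- NULL
  if (!is.null(config$pockets)) {
    pocket_rank <- prioritize_pockets(
      read_pockets(config$pockets),
      graph_betweenness(graphs$bound),
      relay_residues(relay_report)
    )
  }
  structure(
    list(config_hash = config$hash, units = "nm, ps, kT; residues 1-based",
         observables = obs, nri = nri, graphs = graphs, metrics = metrics,
         cross_region = cross, paths = paths, relay_report = relay_report,
         delta_rmsf = delta_rmsf, pocket_rank = pocket_rank,
         source_residue = source_res),
    class = "ComparisonReport"
  )
}

#' Region-averaged RMSF change (bound minus apo)
#'
#' @param rmsf_apo,rmsf_bound [rmsf_profile()] results on a shared residue
#'   set.
#' @param regions named list of residue-number vectors or [region_set()].
#' @return data frame with columns `region`, `mean_rmsf_apo`,
#'   `mean_rmsf_bound`, `delta` (nm).
#' @export
region_delta_rmsf <- function(rmsf_apo, rmsf_bound, regions) {
  regions <- as_region_list(regions)
  rows <- lapply(names(regions), function(nm) {
    sel_a <- rmsf_apo$resno %in% regions[[nm]]
    sel_b <- rmsf_bound$resno %in% regions[[nm]]
    a <- mean(rmsf_apo$rmsf[sel_a])
    b <- mean(rmsf_bound$rmsf[sel_b])
    data.frame(region = nm, mean_rmsf_apo = a, mean_rmsf_bound = b,
               delta = b - a, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.ComparisonReport <- function(x, ...) {
  cat("<ComparisonReport>\n")
  cat(sprintf("  total edge weight: apo %.3f, bound %.3f\n",
              x$metrics$apo$total_edge_weight, x$metrics$bound$total_edge_weight))
  cat(sprintf("  mean betweenness:  apo %.5f, bound %.5f\n",
              x$metrics$apo$mean_betweenness, x$metrics$bound$mean_betweenness))
  cat("  delta RMSF by region (bound - apo, nm):\n")
  for (i in seq_len(nrow(x$delta_rmsf))) {
    cat(sprintf("    %-14s %+.4f\n", x$delta_rmsf$region[i], x$delta_rmsf$delta[i]))
  }
  relays <- relay_residues(x$relay_report)
  cat(sprintf("  relay residues (new in bound paths): %s\n",
              if (length(relays)) paste(relays, collapse = ", ") else "none"))
  invisible(x)
}

write_report <- function(report, config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# units: nm, ps, kT; residues 1-based; config %s",
                 report$config_hash)
  tsv <- function(df, name) {
    path <- file.path(out, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    path
  }
  tsv(report$delta_rmsf, "delta_rmsf.tsv")
  tsv(report$relay_report, "relays.tsv")
  for (state in c("apo", "bound")) {
    tsv(data.frame(resno = report$observables[[state]]$rmsf$resno,
                   rmsf = report$observables[[state]]$rmsf$rmsf),
        sprintf("rmsf_%s.tsv", state))
    write_edge_list(report$graphs[[state]],
                    file.path(out, sprintf("graph_%s.tsv", state)))
  }
  if (!is.null(report$pocket_rank)) tsv(report$pocket_rank, "pocket_rank.tsv")
  summary <- list(
    config_hash = report$config_hash,
    metrics = report$metrics,
    delta_rmsf = report$delta_rmsf,
    cross_region = lapply(report$cross_region, function(m) {
      list(regions = rownames(m), values = unname(as.data.frame(m)))
    }),
    paths = lapply(report$paths, function(ps) {
      lapply(ps, function(p) {
        list(path = p$path, distance = p$distance, reachable = p$reachable)
      })
    }),
    relay_residues = relay_residues(report$relay_report),
    source_residue = report$source_residue
  )
  jsonlite::write_json(summary, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  md <- c(
    "# Two-state comparison report", "",
    sprintf("Config hash: `%s`", report$config_hash),
    sprintf("Units: %s", report$units), "",
    sprintf("Total edge weight: apo %.4f, bound %.4f",
            report$metrics$apo$total_edge_weight,
            report$metrics$bound$total_edge_weight),
    sprintf("Mean betweenness: apo %.6f, bound %.6f",
            report$metrics$apo$mean_betweenness,
            report$metrics$bound$mean_betweenness), "",
    "Tables: delta_rmsf.tsv, relays.tsv, rmsf_apo.tsv, rmsf_bound.tsv,",
    "graph_apo.tsv, graph_bound.tsv"
  )
  writeLines(md, file.path(out, "report.md"))
  invisible(out)
}

# ---- fixtures -------------------------------------------------------------

# Build the relay-demo scenario: a 30-node system whose core is the cluster
# of nodes nearest the centroid, with three peripheral k-means clusters, and
# a planted relay chain (core center -> relay 1 -> relay 2 -> a distal
# region center) added only in the bound state. A two-node chain is used
# deliberately: a single relay would couple source and target through two
# stiff springs in series, and the induced end-to-end correlation is strong
# enough that graph inference can mistake it for a direct edge, shortcutting
# the path; across three springs the induced correlation decays and the
# inferred route has to pass through the chain.
relay_demo_scenario <- function(n_nodes = 30L, seed = 1L,
                                stiffening_factor = 4, softening_factor = 0.25,
                                n_core = 6L, n_peripheral = 3L, ...) {
  sys <- random_geometric_system(n_nodes, seed = seed, ...)
  coords <- sys$initial_coords
  centroid <- colMeans(coords)
  d_cen <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  core <- sort(order(d_cen)[seq_len(n_core)])
  rest <- setdiff(seq_len(n_nodes), core)
  km <- with_seed(seed + 1000L, {
    stats::kmeans(coords[rest, , drop = FALSE], centers = n_peripheral,
                  nstart = 5)
  })
  clusters <- split(rest, km$cluster)
  ord <- order(vapply(clusters, min, 0L))
  clusters <- clusters[ord]
  # Peripheral regions are the distal outskirts of each cluster (the nodes
  # farthest from the global centroid), not whole clusters: the remaining
  # bulk stays unperturbed, emulating small flexible surface modules on an
  # otherwise stable body. Without that neutral bulk, softening would
  # loosen the core's entire anchoring matrix and collective motion would
  # mask the core's own rigidification.
  peripheral <- lapply(clusters, function(idx) {
    n_take <- max(2L, ceiling(length(idx) / 2))
    sort(idx[order(-d_cen[idx])[seq_len(n_take)]])
  })
  names(peripheral) <- paste0("S", seq_along(peripheral))

  g <- igraph::graph_from_edgelist(sys$edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n_nodes - igraph::vcount(g)))
  rc <- function(region) {
    region[which.min(rowSums(sweep(coords[region, , drop = FALSE], 2,
                                   colMeans(coords[region, , drop = FALSE]))^2))]
  }
  src <- rc(core)
  hops <- igraph::distances(g, v = src)[1, ]
  centers <- vapply(peripheral, rc, 0L)
  # prefer a target whose apo route has >= 2 intermediates
  cand <- names(peripheral)[order(-hops[centers])]
  target_name <- cand[1]
  tgt <- centers[target_name]
  ek <- edge_key(sys$edges)
  edge_free <- function(a, b) {
    a != b && !(edge_key(canonical_edges(rbind(c(a, b)))) %in% ek)
  }
  # The chain enters the target region at an entry node distinct from the
  # region centre that path queries use: the planted chain then couples the
  # source to the region without any direct source-centre interaction, so
  # the inferred shortest path to the centre cannot legitimately skip the
  # chain.
  tgt_region <- peripheral[[target_name]]
  entry_cand <- setdiff(tgt_region, tgt)
  d_entry <- sqrt(rowSums(sweep(coords[entry_cand, , drop = FALSE], 2,
                                coords[src, ])^2))
  entry <- entry_cand[order(d_entry)]
  # candidate relays: outside core and the target region, not the endpoints
  pool <- setdiff(seq_len(n_nodes),
                  c(core, tgt_region, src, tgt))
  best <- NULL
  best_cost <- Inf
  for (t2 in entry) {
    waypoint <- function(f) coords[src, ] * (1 - f) + coords[t2, ] * f
    d1 <- sqrt(rowSums(sweep(coords[pool, , drop = FALSE], 2,
                             waypoint(1 / 3))^2))
    d2 <- sqrt(rowSums(sweep(coords[pool, , drop = FALSE], 2,
                             waypoint(2 / 3))^2))
    for (i in seq_along(pool)) {
      for (j in seq_along(pool)) {
        if (i == j) next
        r1 <- pool[i]
        r2 <- pool[j]
        if (!edge_free(src, r1) || !edge_free(r1, r2) ||
            !edge_free(r2, t2)) {
          next
        }
        cost <- d1[i] + d2[j]
        if (cost < best_cost) {
          best <- list(relay = c(r1, r2), entry = t2)
          best_cost <- cost
        }
      }
    }
    if (!is.null(best)) break  # nearest admissible entry node wins
  }
  assert(!is.null(best), "no admissible relay chain in this geometry")
  scenario <- make_scenario(
    n_nodes, core, peripheral,
    relay_spec = rbind(c(src, best$relay[1]), c(best$relay[1], best$relay[2]),
                       c(best$relay[2], best$entry)),
    stiffening_factor = stiffening_factor,
    softening_factor = softening_factor, seed = seed,
    # fully connect the core and each peripheral region internally: packed
    # cores are dense (making the core structurally autonomous, so its
    # stiffening shows as a local RMSF drop), and the peripheral modules
    # need internal springs for the softening factor to act on
    extra_edges = do.call(rbind, lapply(c(list(core), peripheral),
                                        function(r) t(utils::combn(r, 2L)))),
    ...
  )
  attr(scenario, "relay_route") <- list(source = src, relay = best$relay,
                                        entry = best$entry, target = tgt,
                                        target_region = target_name)
  scenario
}

#' Ground-truth scenario presets
#'
#' `"minimal"` is a 12-node system with one softened peripheral region and
#' no relay; `"relay-demo"` is a 30-node system with 4x core stiffening,
#' 0.25x peripheral softening and a planted two-edge relay route that only
#' exists in the bound state.
#'
#' @param preset `"minimal"` or `"relay-demo"`.
#' @param seed integer seed.
#' @return A `ScenarioPair`; for `"relay-demo"` the attribute
#'   `"relay_route"` records the planted source, relay and target nodes.
#' @export
scenario_preset <- function(preset, seed = 1L) {
  switch(preset,
    "minimal" = make_scenario(12L, core_region = 1:4,
                              peripheral_regions = list(P1 = 5:8),
                              relay_spec = NULL, stiffening_factor = 4,
                              softening_factor = 0.25, seed = seed),
    "relay-demo" = relay_demo_scenario(seed = seed),
    stopf("unknown preset '%s' (available: minimal, relay-demo)", preset)
  )
}

#' Write a ready-to-run synthetic fixture set
#'
#' Simulates the chosen scenario preset (3 replicates per state), writes
#' PDB + DCD files for every replicate, the ground-truth JSON and a
#' matching YAML run configuration.
#'
#' @param preset `"minimal"` or `"relay-demo"`.
#' @param out_dir output directory (created).
#' @param seed integer seed; replicate r of each state uses seed + r.
#' @param n_frames saved frames per replicate (default 600 for minimal,
#'   2000 for relay-demo).
#' @param save_stride integration steps per saved frame.
#' @return list with the scenario, the file manifest and the config path.
#' @export
generate_fixtures <- function(preset, out_dir, seed = 1L, n_frames = NULL,
                              save_stride = 5L) {
  scenario <- scenario_preset(preset, seed = seed)
  n_frames <- n_frames %||% if (preset == "minimal") 600L else 2000L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (state in c("apo", "bound")) {
    sys <- scenario[[state]]
    manifest[[state]] <- lapply(1:3, function(r) {
      traj <- simulate_langevin(sys, n_frames, save_stride = save_stride,
                                seed = seed + r)
      top <- file.path(out_dir, sprintf("%s_rep%d.pdb", state, r))
      dcd <- file.path(out_dir, sprintf("%s_rep%d.dcd", state, r))
      export_trajectory(traj, top, dcd)
      list(topology = top, coords = dcd)
    })
  }
  truth_path <- file.path(out_dir, "ground_truth.json")
  write_scenario_json(scenario, truth_path)
  regions <- c(list(core = scenario$core_region), scenario$peripheral_regions)
  cfg_list <- list(
    preset = preset, seed = seed, regions = regions,
    apo_trajectories = manifest$apo, bound_trajectories = manifest$bound,
    ground_truth = truth_path
  )
  cfg_path <- file.path(out_dir, "run_config.yaml")
  yaml::write_yaml(cfg_list, cfg_path)
  list(scenario = scenario, manifest = manifest, config_path = cfg_path,
       ground_truth = truth_path)
}
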