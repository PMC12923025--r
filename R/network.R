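#' Named residue regions
#'
#' Region definitions used for cross-region analysis and path endpoints.
#' The defaults are the SIR2 modules: the catalytic beta1-alpha2 loop
#' (residues 35-63) and five distal regions S1 (80-100), S2 (140-160),
#' S3 (160-190), S4 (210-220) and S5 (250-265); bounds are inclusive and
#' 1-based. S2 and S3 deliberately share residue 160; overlaps between
#' other regions are rejected unless `allow_overlap` names them.
#'
#' @param ... named integer vectors of residue numbers. When empty, the
#'   default SIR2 regions are used.
#' @param allow_overlap character vector of `"A|B"` region-name pairs whose
#'   overlap is declared intentional.
#' @return An object of class `RegionSet` (list with field `regions`).
#' @export
region_set <- function(..., allow_overlap = c("S2|S3")) {
  regions <- list(...)
  if (length(regions) == 0L) {
    regions <- list(
      beta1_alpha2 = 35:63,
      S1 = 80:100, S2 = 140:160, S3 = 160:190,
      S4 = 210:220, S5 = 250:265
    )
  }
  assert(!is.null(names(regions)) && all(nzchar(names(regions))),
         "all regions must be named")
  for (nm in names(regions)) {
    assert(length(regions[[nm]]) > 0L, "region '%s' is empty", nm)
    regions[[nm]] <- as.integer(regions[[nm]])
  }
  nms <- names(regions)
  for (a in seq_along(nms)) {
    for (b in seq_len(a - 1L)) {
      ov <- intersect(regions[[a]], regions[[b]])
      key <- c(paste(nms[b], nms[a], sep = "|"), paste(nms[a], nms[b], sep = "|"))
      if (length(ov) > 0L && !any(key %in% allow_overlap)) {
        stopf("regions '%s' and '%s' overlap (residues %s) without being declared",
              nms[b], nms[a], paste(ov, collapse = ", "))
      }
    }
  }
  structure(list(regions = regions), class = "RegionSet")
}

#' @export
print.RegionSet <- function(x, ...) {
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %-14s %d residues [%d..%d]\n", nm, length(r), min(r), max(r)))
  }
  invisible(x)
}

as_region_list <- function(regions) {
  if (inherits(regions, "RegionSet")) regions$regions else regions
}

#' Build a weighted directed graph from a latent interaction graph
#'
#' Each ordered residue pair becomes a directed edge weighted by its
#' interaction probability (1 minus the non-interacting-type probability);
#' edges below `min_probability` are dropped. The default threshold is the
#' uniform prior 1 / n_edge_types, so only pairs with above-prior evidence
#' of interaction are retained. All residues remain as nodes.
#'
#' @param latent a [latent_interaction_graph()].
#' @param min_probability retention threshold in `[0, 1)`.
#' @param top_edges alternative to `min_probability`: keep this many of
#'   the strongest directed edges (density-based sparsification; useful
#'   because latent probabilities are calibrated only relative to one
#'   another). When given, `min_probability` is ignored.
#' @return An igraph directed graph; vertex names are residue numbers and
#'   edges carry a `weight` attribute equal to the interaction probability.
#' @export
build_graph <- function(latent, min_probability = NULL, top_edges = NULL) {
  assert(inherits(latent, "LatentInteractionGraph"),
         "latent must be a LatentInteractionGraph")
  w <- 1 - latent$probs[, 1]
  if (!is.null(top_edges)) {
    assert(top_edges >= 1, "top_edges must be at least 1")
    thr <- sort(w, decreasing = TRUE)[min(top_edges, length(w))]
    keep <- w >= thr & w > 0
  } else {
    if (is.null(min_probability)) min_probability <- 1 / ncol(latent$probs)
    assert(min_probability >= 0 && min_probability < 1,
           "min_probability must be in [0, 1)")
    keep <- w >= min_probability & w > 0
  }
  g <- igraph::make_empty_graph(n = latent$n_nodes, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(latent$residues))
  if (any(keep)) {
    g <- igraph::add_edges(
      g, rbind(latent$send[keep], latent$recv[keep]),
      weight = w[keep]
    )
  }
  g
}

#' Total edge weight of a communication graph
#'
#' @param graph an igraph graph with a `weight` edge attribute.
#' @return Sum of retained directed edge weights (0 for an empty graph).
#' @export
total_edge_weight <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(0)
  sum(igraph::E(graph)$weight)
}

#' Betweenness centrality on -log-probability distances
#'
#' Directed weighted betweenness where each edge of interaction probability
#' p contributes a distance -log(p), so high-probability links are short.
#' Values are normalized by (n-1)(n-2), the number of ordered transit pairs
#' in a directed graph; ties between equal-length shortest paths are split
#' fractionally.
#'
#' @param graph an igraph directed graph with `weight` in (0, 1].
#' @return Named numeric vector of per-residue centralities.
#' @export
graph_betweenness <- function(graph) {
  n <- igraph::vcount(graph)
  out <- stats::setNames(numeric(n), igraph::V(graph)$name)
  if (igraph::ecount(graph) == 0L || n < 3L) return(out)
  w <- igraph::E(graph)$weight
  assert(all(w > 0), "edge weights must be positive to take -log")
  b <- igraph::betweenness(graph, directed = TRUE, weights = -log(w),
                           normalized = TRUE)
  out[names(b)] <- b
  out
}

# Dense weight matrix (absent edges 0) indexed by residue name.
weight_matrix <- function(x) {
  if (inherits(x, "LatentInteractionGraph")) return(interaction_matrix(x))
  if (igraph::is_igraph(x)) {
    m <- as.matrix(igraph::as_adjacency_matrix(x, attr = "weight", sparse = TRUE))
    return(m)
  }
  as.matrix(x)
}

#' Directed cross-region interaction strengths
#'
#' Entry (A, B) is the mean edge weight over ordered residue pairs
#' (i in A, j in B, i != j), counting absent edges as 0; the diagonal is the
#' within-region mean excluding self pairs. Regions that overlap (for
#' example S2/S3 sharing a residue) are handled by the i != j rule.
#'
#' @param x a [latent_interaction_graph()], an igraph graph from
#'   [build_graph()], or a dense weight matrix with residue-name dimnames.
#' @param regions a [region_set()] or named list of residue-number vectors.
#' @return Directed `regions x regions` matrix (rows = source region).
#' @export
cross_region_strength <- function(x, regions) {
  regions <- as_region_list(regions)
  m <- weight_matrix(x)
  residues <- as.integer(rownames(m) %||% seq_len(nrow(m)))
  idx <- lapply(regions, function(r) which(residues %in% r))
  for (nm in names(idx)) {
    assert(length(idx[[nm]]) > 0L, "region '%s' has no nodes in the graph", nm)
  }
  out <- matrix(0, length(regions), length(regions),
                dimnames = list(names(regions), names(regions)))
  for (a in names(regions)) {
    for (b in names(regions)) {
      ia <- idx[[a]]
      ib <- idx[[b]]
      pairs_total <- 0
      acc <- 0
      sub <- m[ia, ib, drop = FALSE]
      same <- outer(ia, ib, `==`)
      acc <- sum(sub[!same])
      pairs_total <- sum(!same)
      out[a, b] <- if (pairs_total > 0) acc / pairs_total else NA_real_
    }
  }
  out
}

#' Residue nearest the geometric center of a region
#'
#' @param mean_coords `n x 3` matrix of time-averaged Calpha coordinates,
#'   with rownames giving residue numbers (defaults to 1..n).
#' @param region integer vector of residue numbers.
#' @return The region residue whose mean position is closest to the region
#'   centroid; ties broken by lowest residue number.
#' @export
region_center_residue <- function(mean_coords, region) {
  residues <- as.integer(rownames(mean_coords) %||% seq_len(nrow(mean_coords)))
  rows <- which(residues %in% as.integer(region))
  assert(length(rows) > 0L, "region has no residues with coordinates")
  sub <- mean_coords[rows, , drop = FALSE]
  centroid <- colMeans(sub)
  d <- sqrt(rowSums(sweep(sub, 2, centroid)^2))
  # order() is stable, so equal distances resolve to the lowest residue
  residues[rows][order(d, residues[rows])[1]]
}

#' Shortest communication path (Dijkstra on -log-probability distances)
#'
#' Computes the minimum-total-distance path between two residues where each
#' edge of probability p costs -log(p). Ties are resolved deterministically:
#' among equal-distance routes the one with fewer hops wins, then the one
#' whose predecessor residue number is smallest.
#'
#' @param graph an igraph directed graph from [build_graph()].
#' @param source,target residue numbers (must differ).
#' @return An object of class `CommunicationPath`: list with `source`,
#'   `target`, `path` (residue numbers source..target, or NULL when the
#'   target is unreachable), `distance` (Inf when unreachable),
#'   `edge_probs` and `reachable`.
#' @export
shortest_path <- function(graph, source, target) {
  assert(source != target, "source and target must differ")
  vnames <- igraph::V(graph)$name
  s <- match(as.character(source), vnames)
  t <- match(as.character(target), vnames)
  assert(!is.na(s), "source residue %s is not in the graph", source)
  assert(!is.na(t), "target residue %s is not in the graph", target)

  n <- length(vnames)
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- if (igraph::ecount(graph) > 0L) -log(igraph::E(graph)$weight) else numeric(0)
  adj <- vector("list", n)
  if (nrow(el) > 0L) {
    by_src <- split(seq_len(nrow(el)), el[, 1])
    for (src in names(by_src)) {
      eidx <- by_src[[src]]
      adj[[as.integer(src)]] <- cbind(el[eidx, 2], w[eidx], eidx)
    }
  }
  res_no <- suppressWarnings(as.integer(vnames))
  if (anyNA(res_no)) res_no <- seq_len(n)

  dist <- rep(Inf, n)
  hops <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  pred_edge <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  dist[s] <- 0
  hops[s] <- 0
  eps <- 1e-12
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0L) break
    # deterministic extraction: min distance, then fewer hops, then residue no
    u <- cand[order(dist[cand], hops[cand], res_no[cand])[1]]
    done[u] <- TRUE
    if (u == t) break
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1]
      nd <- dist[u] + nb[r, 2]
      nh <- hops[u] + 1
      better <- nd < dist[v] - eps ||
        (abs(nd - dist[v]) <= eps &&
           (nh < hops[v] ||
              (nh == hops[v] && !is.na(pred[v]) && res_no[u] < res_no[pred[v]])))
      if (better) {
        dist[v] <- min(nd, dist[v])
        hops[v] <- nh
        pred[v] <- u
        pred_edge[v] <- nb[r, 3]
      }
    }
  }
  if (!is.finite(dist[t])) {
    return(structure(
      list(source = as.integer(source), target = as.integer(target),
           path = NULL, distance = Inf, edge_probs = numeric(0),
           reachable = FALSE),
      class = "CommunicationPath"
    ))
  }
  nodes <- t
  edges <- integer(0)
  while (nodes[1] != s) {
    edges <- c(pred_edge[nodes[1]], edges)
    nodes <- c(pred[nodes[1]], nodes)
  }
  probs <- igraph::E(graph)$weight[edges]
  structure(
    list(source = as.integer(source), target = as.integer(target),
         path = res_no[nodes], distance = sum(-log(probs)),
         edge_probs = probs, reachable = TRUE),
    class = "CommunicationPath"
  )
}

#' @export
print.CommunicationPath <- function(x, ...) {
  if (!x$reachable) {
    cat(sprintf("<CommunicationPath> %d -> %d: unreachable\n", x$source, x$target))
  } else {
    cat(sprintf("<CommunicationPath> %s (distance %.4f)\n",
                paste(x$path, collapse = " -> "), x$distance))
  }
  invisible(x)
}

path_intermediates <- function(path) {
  if (!path$reachable || length(path$path) <= 2L) return(integer(0))
  path$path[-c(1L, length(path$path))]
}

#' Relay residues appearing in one state's paths but not the other's
#'
#' Compares two sets of shortest communication paths (typically apo vs
#' bound) indexed by the same region-pair keys. For each key, relays are
#' intermediate residues present in the state-b path but absent from the
#' state-a path; intermediates lost from state a are reported too.
#'
#' @param paths_state_a,paths_state_b named lists of
#'   [shortest_path()] results with identical names.
#' @return An object of class `RelayReport`: data frame with one row per
#'   region pair (`key`, `path_a`, `path_b`, `relays`, `lost`,
#'   `unchanged`), plus attribute `"relay_residues"` with the union of all
#'   new relays.
#' @export
detect_relays <- function(paths_state_a, paths_state_b) {
  keys <- names(paths_state_a)
  assert(!is.null(keys) && all(nzchar(keys)), "path sets must be named")
  missing_b <- setdiff(keys, names(paths_state_b))
  missing_a <- setdiff(names(paths_state_b), keys)
  assert(length(missing_b) == 0L && length(missing_a) == 0L,
         "path sets are keyed differently (missing: %s)",
         paste(c(missing_b, missing_a), collapse = ", "))
  rows <- lapply(keys, function(k) {
    a <- paths_state_a[[k]]
    b <- paths_state_b[[k]]
    ia <- path_intermediates(a)
    ib <- path_intermediates(b)
    data.frame(
      key = k,
      path_a = paste(a$path %||% "unreachable", collapse = "-"),
      path_b = paste(b$path %||% "unreachable", collapse = "-"),
      relays = paste(setdiff(ib, ia), collapse = ","),
      lost = paste(setdiff(ia, ib), collapse = ","),
      unchanged = identical(a$path, b$path),
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  relays <- sort(unique(unlist(lapply(keys, function(k) {
    setdiff(path_intermediates(paths_state_b[[k]]),
            path_intermediates(paths_state_a[[k]]))
  }))))
  attr(report, "relay_residues") <- as.integer(relays)
  class(report) <- c("RelayReport", class(report))
  report
}

#' Relay residues extracted from a relay report
#' @param report a [detect_relays()] result.
#' @return integer vector of relay residue numbers.
#' @export
relay_residues <- function(report) attr(report, "relay_residues")

#' Pocket definitions
#'
#' @param id pocket identifier.
#' @param residues integer vector of pocket-lining residue numbers.
#' @param score optional external score (e.g. a cavity-detection ranking
#'   score or volume) used for tie-breaking.
#' @return An object of class `PocketDefinition`.
#' @export
pocket_definition <- function(id, residues, score = NA_real_) {
  residues <- as.integer(residues)
  assert(length(residues) > 0L, "pocket residue set must be non-empty")
  structure(list(id = id, residues = residues, score = as.numeric(score)),
            class = "PocketDefinition")
}

#' Read pocket residue lists
#'
#' Parses either a plain TSV with columns `pocket`, `residues`
#' (comma-separated residue numbers) and optionally `score`, or an
#' fpocket-style info text in which `Pocket <n>` headers are followed by
#' indented `key : value` lines (a `Score` line is kept) and a
#' `Residues : ...` line lists the lining residues.
#'
#' @param path input file.
#' @return list of [pocket_definition()] objects.
#' @export
read_pockets <- function(path) {
  assert(file.exists(path), "pocket file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^Pocket\\s+\\d+", lines))) {
    return(parse_pockets_info(lines))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assert(all(c("pocket", "residues") %in% names(df)),
         "pocket TSV needs columns 'pocket' and 'residues'")
  lapply(seq_len(nrow(df)), function(i) {
    pocket_definition(
      df$pocket[i],
      as.integer(strsplit(as.character(df$residues[i]), "[,; ]+")[[1]]),
      score = if ("score" %in% names(df)) df$score[i] else NA_real_
    )
  })
}

parse_pockets_info <- function(lines) {
  starts <- grep("^Pocket\\s+\\d+", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    block <- lines[starts[i]:ends[i]]
    id <- as.integer(sub("^Pocket\\s+(\\d+).*", "\\1", block[1]))
    score_line <- grep("Score\\s*:", block, value = TRUE)
    score <- if (length(score_line) > 0) {
      as.numeric(sub(".*:\\s*", "", score_line[1]))
    } else {
      NA_real_
    }
    res_line <- grep("Residues\\s*:", block, value = TRUE)
    assert(length(res_line) > 0, "pocket %d has no 'Residues :' line", id)
    res <- as.integer(strsplit(sub(".*:\\s*", "", res_line[1]), "[,; ]+")[[1]])
    pocket_definition(id, res, score)
  })
}

#' Rank pockets by overlap with relay and high-centrality residues
#'
#' Each pocket is scored `w_relay * |pocket intersect relays| +
#' w_hub * |pocket intersect hubs|`, where hubs are the residues in the top
#' decile of betweenness centrality. Pockets are ranked by descending
#' score; ties are broken by the external pocket score (descending, when
#' present), then by pocket id.
#'
#' @param pockets list of [pocket_definition()] objects.
#' @param centrality named per-residue centrality vector (names = residue
#'   numbers), e.g. from [graph_betweenness()].
#' @param relays integer vector of relay residue numbers.
#' @param hub_quantile centrality quantile above which a residue is a hub.
#' @param w_relay,w_hub term weights.
#' @return Data frame (one row per pocket, ranked) with columns `pocket`,
#'   `score`, `n_relay`, `n_hub`, `relay_hits`, `hub_hits`,
#'   `external_score`.
#' @export
prioritize_pockets <- function(pockets, centrality, relays,
                               hub_quantile = 0.9, w_relay = 1, w_hub = 1) {
  assert(length(pockets) > 0L, "pockets must be non-empty")
  resid_c <- as.integer(names(centrality))
  thr <- stats::quantile(centrality, hub_quantile, names = FALSE)
  hubs <- resid_c[centrality >= thr]
  rows <- lapply(pockets, function(p) {
    rhit <- intersect(p$residues, as.integer(relays))
    hhit <- intersect(p$residues, hubs)
    data.frame(
      pocket = p$id,
      score = w_relay * length(rhit) + w_hub * length(hhit),
      n_relay = length(rhit), n_hub = length(hhit),
      relay_hits = paste(rhit, collapse = ","),
      hub_hits = paste(hhit, collapse = ","),
      external_score = p$score,
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  ext <- ifelse(is.na(df$external_score), -Inf, df$external_score)
  df <- df[order(-df$score, -ext, df$pocket), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a communication graph as a Cytoscape-compatible edge list
#'
#' Writes a TSV with columns `source`, `target`, `probability` (residue
#' numbers, 1-based).
#'
#' @param graph an igraph graph from [build_graph()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   probability = if (igraph::ecount(graph) > 0L)
                     igraph::E(graph)$weight else numeric(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a communication graph as GraphML
#'
#' @param graph an igraph graph.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
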