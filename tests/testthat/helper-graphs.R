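# Brute-force graph oracles used to validate Dijkstra paths and betweenness.

# All simple paths s -> t in a directed weight matrix (0 = no edge).
enumerate_paths <- function(w, s, t) {
  n <- nrow(w)
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (w[u, v] > 0 && !(v %in% path)) walk(c(path, v))
    }
  }
  walk(s)
  out
}

path_cost <- function(w, path) {
  if (length(path) < 2) return(0)
  sum(-log(w[cbind(path[-length(path)], path[-1])]))
}

# Exhaustive shortest-path distance (Inf when unreachable).
brute_distance <- function(w, s, t) {
  paths <- enumerate_paths(w, s, t)
  if (length(paths) == 0) return(Inf)
  min(vapply(paths, function(p) path_cost(w, p), 0))
}

# Exhaustive directed betweenness with fractional tie splitting, normalized
# by (n-1)(n-2).
brute_betweenness <- function(w, tol = 1e-10) {
  n <- nrow(w)
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      paths <- enumerate_paths(w, s, t)
      if (length(paths) == 0) next
      costs <- vapply(paths, function(p) path_cost(w, p), 0)
      best <- min(costs)
      shortest <- paths[costs <= best + tol]
      for (p in shortest) {
        inner <- setdiff(p, c(s, t))
        b[inner] <- b[inner] + 1 / length(shortest)
      }
    }
  }
  b / ((n - 1) * (n - 2))
}

# Random sparse directed graph as an igraph object + weight matrix.
random_digraph <- function(n, p = 0.3, seed = 1) {
  with_seed(seed, {
    w <- matrix(0, n, n)
    mask <- matrix(stats::runif(n * n) < p, n, n)
    diag(mask) <- FALSE
    w[mask] <- stats::runif(sum(mask), 0.05, 0.99)
  })
  probs <- cbind(1 - as.vector(t(w)[t(w) > 0]))  # unused placeholder
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "directed")
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::E(g)$weight <- w[t(apply(igraph::as_edgelist(g, names = FALSE), 1,
                                   identity))][1]
  # set weights correctly (edge order = as_edgelist order)
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- w[el]
  list(graph = g, w = w)
}
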