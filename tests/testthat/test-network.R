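# Communication-network analysis: graphs, centrality, paths, relays, pockets.

toy_latent <- function(probs_interact, n) {
  # build a LatentInteractionGraph from an interaction-probability vector
  # over ordered pairs (sorted by sender then receiver)
  latent_interaction_graph(cbind(1 - probs_interact, probs_interact), n)
}

test_that("graph construction keeps exactly the above-threshold edges", {
  n <- 4
  with_seed(2, p <- stats::runif(n * (n - 1)))
  latent <- toy_latent(p, n)
  g0 <- build_graph(latent, min_probability = 0)
  expect_equal(igraph::ecount(g0), n * (n - 1))
  expect_equal(sort(igraph::E(g0)$weight), sort(p))
  g_none <- build_graph(latent, min_probability = 0.9999)
  expect_equal(igraph::ecount(g_none), 0)
  g_half <- build_graph(latent)  # default threshold 1/K = 0.5
  expect_equal(igraph::ecount(g_half), sum(p >= 0.5))
  expect_equal(total_edge_weight(g_half), sum(p[p >= 0.5]))
  expect_equal(total_edge_weight(g_none), 0)
})

test_that("betweenness matches hand enumeration on a directed path", {
  latent <- toy_latent(rep(0, 6), 3)
  latent$probs[c(2, 6), ] <- c(0.2, 0.2, 0.8, 0.8)  # edges 1->3? order check below
  # ordered pairs for n=3: (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
  p <- rep(0, 6)
  p[c(1, 4)] <- 0.7  # 1->2 and 2->3
  g <- build_graph(toy_latent(p, 3))
  b <- graph_betweenness(g)
  expect_equal(unname(b), c(0, 0.5, 0))
})

test_that("Dijkstra and betweenness agree with exhaustive enumeration", {
  # a quick screen; the full 100-graph oracle sweep runs with the
  # end-to-end validation suite
  for (seed in 1:25) {
    n <- sample(4:8, 1)
    rg <- random_digraph(n, p = 0.35, seed = seed)
    b <- graph_betweenness(rg$graph)
    expect_equal(unname(b), brute_betweenness(rg$w), tolerance = 1e-9)
    s <- sample(n, 1)
    t <- sample(setdiff(seq_len(n), s), 1)
    sp <- shortest_path(rg$graph, s, t)
    bd <- brute_distance(rg$w, s, t)
    if (is.infinite(bd)) {
      expect_false(sp$reachable)
    } else {
      expect_equal(sp$distance, bd, tolerance = 1e-9)
      # returned path is itself optimal and consistent
      expect_equal(path_cost(rg$w, sp$path), sp$distance, tolerance = 1e-9)
    }
  }
})

test_that("path distance and edge probabilities are duals", {
  rg <- random_digraph(7, p = 0.4, seed = 5)
  sp <- shortest_path(rg$graph, 1, 7)
  if (sp$reachable) {
    expect_equal(exp(-sp$distance), prod(sp$edge_probs), tolerance = 1e-9)
    expect_equal(sp$path[1], 1)
    expect_equal(sp$path[length(sp$path)], 7)
  }
  # unit-probability edge is a zero-cost link
  p <- rep(0, 6)
  p[1] <- 1  # 1->2
  g <- build_graph(toy_latent(p, 3), min_probability = 0.5)
  sp2 <- shortest_path(g, 1, 2)
  expect_equal(sp2$distance, 0)
  expect_equal(sp2$path, c(1, 2))
})

test_that("a two-hop high-probability route beats a direct weak edge", {
  # ordered pairs n=3: (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
  p <- c(0.9, 0.1, 0, 0.9, 0, 0)
  g <- build_graph(toy_latent(p, 3), min_probability = 0.05)
  sp <- shortest_path(g, 1, 3)
  expect_equal(sp$path, c(1, 2, 3))  # 2*0.105 < 2.303
})

test_that("cross-region strengths average ordered pairs with absent edges as zero", {
  n <- 4
  p <- rep(0.5, n * (n - 1))
  m <- cross_region_strength(toy_latent(p, n),
                             list(A = 1:2, B = 3:4))
  expect_true(all(abs(m - 0.5) < 1e-12))

  # single cross pair of weight 0.7, everything else absent
  p2 <- rep(0, n * (n - 1))
  # ordered pairs sorted by sender: (1,2),(1,3),(1,4),(2,1),(2,3),(2,4),...
  p2[2] <- 0.7  # pair (1,3)
  m2 <- cross_region_strength(toy_latent(p2, n), list(A = 1:2, B = 3:4))
  expect_equal(m2["A", "B"], 0.7 / 4)
  expect_equal(m2["B", "A"], 0)

  # overlapping regions are handled through the i != j rule
  m3 <- cross_region_strength(toy_latent(p, n), list(A = 1:3, B = 3:4))
  expect_true(is.finite(m3["A", "B"]))
  expect_error(cross_region_strength(toy_latent(p, n), list(A = 9:10)),
               "no nodes")
})

test_that("region centers resolve to the residue nearest the centroid", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  rownames(coords) <- 1:3
  expect_equal(region_center_residue(coords, 1:3), 2)
  expect_equal(region_center_residue(coords, 3), 3)
  with_seed(8, {
    pts <- matrix(stats::runif(30), 10, 3)
    rownames(pts) <- 1:10
    for (i in 1:5) {
      region <- sample(10, sample(3:8, 1))
      centroid <- colMeans(pts[region, , drop = FALSE])
      d <- sqrt(rowSums(sweep(pts[region, , drop = FALSE], 2, centroid)^2))
      expect_equal(region_center_residue(pts, region),
                   region[order(d, region)][1])
    }
  })
})

test_that("relay detection reports new and lost intermediates", {
  mk_path <- function(nodes) {
    structure(list(source = nodes[1], target = nodes[length(nodes)],
                   path = nodes, distance = 1,
                   edge_probs = rep(0.5, length(nodes) - 1),
                   reachable = TRUE),
              class = "CommunicationPath")
  }
  a <- list(S2 = mk_path(c(44L, 146L)), S3 = mk_path(c(44L, 52L, 178L)))
  b <- list(S2 = mk_path(c(44L, 214L, 146L)), S3 = mk_path(c(44L, 52L, 178L)))
  rep <- detect_relays(a, b)
  expect_equal(rep$relays[rep$key == "S2"], "214")
  expect_true(rep$unchanged[rep$key == "S3"])
  expect_equal(relay_residues(rep), 214L)
  expect_identical(relay_residues(detect_relays(a, a)), integer(0))
  expect_error(detect_relays(a, b[1]), "keyed differently")
})

test_that("pocket prioritization ranks by relay and hub overlap", {
  pockets <- list(
    pocket_definition(1, c(10, 11)),          # no overlap
    pocket_definition(2, c(214, 50)),         # 1 relay
    pocket_definition(3, c(224, 252))         # 1 relay + 1 hub
  )
  centrality <- stats::setNames(c(rep(0.001, 9), 0.05), as.character(c(1:9, 252)))
  rank <- prioritize_pockets(pockets, centrality, relays = c(214, 224))
  expect_equal(rank$pocket, c(3, 2, 1))
  expect_equal(rank$score, c(2, 1, 0))
  # ties break by external score
  tied <- list(pocket_definition(1, 214, score = 0.2),
               pocket_definition(2, 224, score = 0.9))
  rank2 <- prioritize_pockets(tied, centrality, relays = c(214, 224))
  expect_equal(rank2$pocket, c(2, 1))
})

test_that("pocket files parse from TSV and info-style text", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("pocket\tresidues\tscore",
               "1\t10,11,12\t0.8",
               "2\t214,224\t0.5"), tsv)
  pk <- read_pockets(tsv)
  expect_length(pk, 2)
  expect_equal(pk[[2]]$residues, c(214L, 224L))

  info <- tempfile(fileext = ".txt")
  writeLines(c("Pocket 1 :", "\tScore : 0.49", "\tResidues : 10, 11, 12",
               "Pocket 2 :", "\tScore : 0.31", "\tResidues : 214 224"), info)
  pk2 <- read_pockets(info)
  expect_length(pk2, 2)
  expect_equal(pk2[[1]]$score, 0.49)
  expect_equal(pk2[[2]]$residues, c(214L, 224L))
})

test_that("region sets enforce declared overlaps and defaults", {
  rs <- region_set()
  expect_equal(rs$regions$beta1_alpha2, 35:63)
  expect_equal(rs$regions$S5, 250:265)
  expect_equal(intersect(rs$regions$S2, rs$regions$S3), 160)
  expect_error(region_set(A = 1:5, B = 4:8), "overlap")
  ok <- region_set(A = 1:5, B = 4:8, allow_overlap = "A|B")
  expect_equal(intersect(ok$regions$A, ok$regions$B), 4:5)
})

test_that("graph exports are readable edge lists", {
  p <- c(0.9, 0.1, 0, 0.9, 0, 0)
  g <- build_graph(toy_latent(p, 3), min_probability = 0.5)
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(g, tsv)
  el <- utils::read.delim(tsv)
  expect_equal(nrow(el), 2)
  expect_equal(sort(el$probability), c(0.9, 0.9))
  gml <- tempfile(fileext = ".graphml")
  write_graphml(g, gml)
  expect_true(file.size(gml) > 0)
})
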