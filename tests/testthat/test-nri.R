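# NRI engine: encoder, Gumbel-softmax, decoder, loss, training mechanics.

tiny_cfg <- function(...) {
  nri_config(hidden_dim = 8L, epochs = 5L, prediction_steps = 3L,
             warmup_epochs = 1L, seed = 5L, profile = "ci", ...)
}

tiny_segments <- function(n_nodes = 4, window = 12, n_seg = 3, seed = 2) {
  sys <- random_geometric_system(n_nodes, seed = seed)
  traj <- simulate_langevin(sys, n_frames = window * n_seg + 5,
                            save_stride = 5, seed = seed + 1)
  feats <- compute_features(traj)
  window_segments(feats$values, window, window)
}

test_that("encoder is pure, row-normalizable and permutation-equivariant", {
  segs <- tiny_segments()
  cfg <- tiny_cfg()
  model <- with_seed(1, nri_model(4, 12, 6, cfg))
  l1 <- nri_encode(model, segs[[1]])
  l2 <- nri_encode(model, segs[[1]])
  expect_identical(l1, l2)
  q <- allokit:::softmax_rows(l1)
  expect_equal(rowSums(q), rep(1, nrow(q)), tolerance = 1e-6)

  # permuting node order permutes pair logits consistently
  perm <- c(3, 1, 4, 2)
  seg_p <- segs[[1]][, perm, , drop = FALSE]
  lp <- nri_encode(model, seg_p)
  pairs <- allokit:::ordered_pairs(4)
  key <- function(s, r) paste(s, r)
  orig <- stats::setNames(seq_along(pairs$send),
                          key(pairs$send, pairs$recv))
  # pair (i,j) in permuted segment corresponds to (perm[i], perm[j])
  idx <- orig[key(perm[pairs$send], perm[pairs$recv])]
  expect_equal(lp, l1[idx, , drop = FALSE], tolerance = 1e-5)
})

test_that("gumbel-softmax samples are simplex points with the right limits", {
  with_seed(4, logits <- matrix(stats::rnorm(20 * 2, sd = 3), 20, 2))
  y <- gumbel_softmax_sample(logits, temperature = 0.5, seed = 9)
  expect_equal(rowSums(y), rep(1, 20), tolerance = 1e-6)
  expect_identical(y, gumbel_softmax_sample(logits, temperature = 0.5, seed = 9))

  # low temperature concentrates on the argmax for well-separated logits
  wide <- matrix(c(rep(4, 50), rep(-4, 50)), 50, 2)
  hits <- 0
  for (s in 1:20) {
    ys <- gumbel_softmax_sample(wide, temperature = 0.01, seed = s)
    hits <- hits + sum(ys[cbind(1:50, max.col(wide))] > 0.99)
  }
  expect_gte(hits / (50 * 20), 0.99)

  h <- gumbel_softmax_sample(logits, temperature = 0.5, seed = 9, hard = TRUE)
  expect_true(all(h %in% c(0, 1)))
  expect_equal(rowSums(h), rep(1, 20))
  expect_equal(attr(h, "soft"), y, tolerance = 1e-12)
})

test_that("the non-interacting edge type carries no influence", {
  cfg <- tiny_cfg()
  model <- with_seed(7, nri_model(4, 12, 6, cfg))
  state <- matrix(stats::rnorm(24), 4, 6)
  z_none <- cbind(rep(1, 12), rep(0, 12))
  base <- nri_decode_step(model, state, z_none)
  expect_equal(dim(base), dim(state))
  bumped <- state
  bumped[2, ] <- bumped[2, ] + 5
  pred <- nri_decode_step(model, bumped, z_none)
  expect_equal(pred[-2, ], base[-2, ], tolerance = 1e-12)

  # with interacting edges, the same perturbation propagates
  z_all <- cbind(rep(0, 12), rep(1, 12))
  pred_all <- nri_decode_step(model, bumped, z_all)
  expect_gt(max(abs(pred_all[-2, ] - nri_decode_step(model, state, z_all)[-2, ])), 1e-6)
})

test_that("training rollout equals chained single decoder steps", {
  cfg <- tiny_cfg()
  segs <- tiny_segments()
  model <- with_seed(3, nri_model(4, 12, 6, cfg))
  pairs <- allokit:::ordered_pairs(4)
  prep <- allokit:::make_segment_prep(segs[[1]], pairs, cfg$prediction_steps)
  z <- cbind(rep(0.3, 12), rep(0.7, 12))
  # batched rollout from the prep starts
  S <- prep$S0
  for (m in 1:prep$M) {
    S <- allokit:::dec_forward_step(model$params, S, z[prep$pair_rep, ],
                                    prep$send_b, prep$recv_b)$S_next
  }
  # manual chain on the first chunk only
  chunk1 <- segs[[1]][1, , ]
  for (m in 1:prep$M) chunk1 <- nri_decode_step(model, chunk1, z)
  expect_equal(S[1:4, ], chunk1, tolerance = 1e-12)
})

test_that("ELBO components behave at their fixed points", {
  x <- array(stats::rnorm(60), c(5, 4, 3))
  q_unif <- matrix(0.5, 12, 2)
  el <- nri_elbo(x, x, q_unif)
  expect_equal(el$recon, 0)
  expect_equal(el$kl, 0, tolerance = 1e-12)
  with_seed(11, {
    for (i in 1:1000) {
      q <- stats::runif(2)
      q <- matrix(q / sum(q), 1)
      expect_gte(nri_elbo(1, 1, q)$kl, -1e-12)
    }
  })
  # KL against a non-uniform prior is zero exactly at the prior
  pr <- c(0.9, 0.1)
  expect_equal(nri_elbo(1, 1, matrix(pr, 1), prior = pr)$kl, 0,
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  n <- 3; Tw <- 6
  cfg <- nri_config(hidden_dim = 4L, epochs = 2L, prediction_steps = 2L,
                    warmup_epochs = 0L, output_variance = 1e-2,
                    gumbel_temperature = 0.7, prior = c(0.8, 0.2), seed = 9)
  model <- with_seed(9, nri_model(n, Tw, 6, cfg))
  pairs <- allokit:::ordered_pairs(n)
  with_seed(21, {
    seg <- array(stats::rnorm(Tw * n * 6, sd = 0.3), c(Tw, n, 6))
    gn <- matrix(-log(-log(stats::runif(length(pairs$send) * 2))), ncol = 2)
  })
  prep <- allokit:::make_segment_prep(seg, pairs, cfg$prediction_steps)
  res <- allokit:::nri_segment_grad(model$params, pairs, prep, cfg,
                                    gumbel_noise = gn)
  loss_of <- function(p) {
    allokit:::nri_segment_grad(p, pairs, prep, cfg, gumbel_noise = gn)$total
  }
  h <- 1e-6
  check_leaf <- function(get, set) {
    P <- get(model$params)
    G <- get(res$grads)
    with_seed(sum(dim(as.matrix(P))), idx <- sample(length(P), min(3, length(P))))
    for (i in idx) {
      up <- set(model$params, i, h)
      dn <- set(model$params, i, -h)
      num <- (loss_of(up) - loss_of(dn)) / (2 * h)
      expect_equal(G[i], num, tolerance = 1e-4)
    }
  }
  check_leaf(function(p) p$enc$emb$l1$W,
             function(p, i, d) { p$enc$emb$l1$W[i] <- p$enc$emb$l1$W[i] + d; p })
  check_leaf(function(p) p$enc$out$l2$W,
             function(p, i, d) { p$enc$out$l2$W[i] <- p$enc$out$l2$W[i] + d; p })
  check_leaf(function(p) p$enc$node$l1$b,
             function(p, i, d) { p$enc$node$l1$b[i] <- p$enc$node$l1$b[i] + d; p })
  check_leaf(function(p) p$dec$msg[[1]]$l1$W,
             function(p, i, d) { p$dec$msg[[1]]$l1$W[i] <- p$dec$msg[[1]]$l1$W[i] + d; p })
  check_leaf(function(p) p$dec$out$l2$b,
             function(p, i, d) { p$dec$out$l2$b[i] <- p$dec$out$l2$b[i] + d; p })
})

test_that("training reduces the loss and is seed-deterministic", {
  segs <- tiny_segments(n_nodes = 5, window = 10, n_seg = 4)
  cfg <- nri_config(hidden_dim = 8L, epochs = 12L, prediction_steps = 3L,
                    warmup_epochs = 2L, seed = 31, profile = "ci")
  fit1 <- train_nri(segs, cfg)
  fit2 <- train_nri(segs, cfg)
  expect_lt(tail(fit1$loss_history$total, 1), fit1$loss_history$total[1])
  expect_equal(fit1$graph$probs, fit2$graph$probs, tolerance = 1e-6)
  expect_equal(rowSums(fit1$graph$probs), rep(1, nrow(fit1$graph$probs)),
               tolerance = 1e-6)
  # learning-rate schedule: decay by the configured factor at the interval
  cfg2 <- nri_config(hidden_dim = 8L, epochs = 5L, lr_decay_every = 2L,
                     warmup_epochs = 0L, seed = 1)
  fit3 <- train_nri(tiny_segments(), cfg2)
  expect_equal(fit3$loss_history$lr,
               5e-4 * 0.2^c(0, 0, 1, 1, 2), tolerance = 1e-12)
})

test_that("consensus averaging preserves distributions", {
  with_seed(6, {
    p1 <- stats::runif(12)
    g1 <- latent_interaction_graph(cbind(1 - p1, p1), 4)
    p2 <- stats::runif(12)
    g2 <- latent_interaction_graph(cbind(1 - p2, p2), 4)
  })
  cons <- consensus_graph(list(g1, g2))
  expect_equal(cons$probs, (g1$probs + g2$probs) / 2)
  expect_equal(rowSums(cons$probs), rep(1, 12), tolerance = 1e-9)
  expect_equal(consensus_graph(list(g1))$probs, g1$probs)

  # opposing certainties average to indifference
  ga <- latent_interaction_graph(cbind(rep(1, 2), rep(0, 2)), 2)
  gb <- latent_interaction_graph(cbind(rep(0, 2), rep(1, 2)), 2)
  expect_equal(consensus_graph(list(ga, gb))$probs,
               matrix(0.5, 2, 2))
  g3 <- latent_interaction_graph(matrix(0.5, 6, 2), 3)
  expect_error(consensus_graph(list(g1, g3)), "mismatch")
})

test_that("reverse-sampling check validates inputs and score range", {
  sys <- random_geometric_system(12, seed = 13)
  traj <- simulate_langevin(sys, 260, save_stride = 5, seed = 2)
  cfg <- nri_config(hidden_dim = 8L, epochs = 4L, warmup_epochs = 1L,
                    prediction_steps = 5L, seed = 3, profile = "ci")
  regions <- list(A = 1:6, B = 7:12)
  res <- reverse_sampling_check(traj, 0.5, cfg, regions,
                                window = 20, stride = 40)
  expect_true(is.na(res$score) || (res$score >= -1 && res$score <= 1))
  expect_equal(dim(res$selected_matrix), c(2, 2))
  expect_error(
    reverse_sampling_check(traj, 0.5, cfg, list(A = 1:6, B = 999),
                           window = 20, stride = 40),
    "no residues"
  )
})
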