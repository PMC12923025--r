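#' Neural relational inference configuration
#'
#' Hyperparameters for the NRI engine. The training schedule (Adam, initial
#' learning rate 5e-4 decayed by 0.2 every 200 epochs, 500 epochs, batch
#' size 1) is the reference protocol; `profile = "ci"` is a reduced preset
#' (100 epochs) sized for routine test runs on small synthetic systems.
#'
#' @param n_edge_types number of latent edge types; type 1 is the
#'   non-interacting type and contributes no decoder messages by
#'   construction.
#' @param hidden_dim width of all hidden layers.
#' @param gumbel_temperature concrete-relaxation temperature used when
#'   sampling latent edges during training.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay_factor multiplicative learning-rate decay.
#' @param lr_decay_every epochs between decays.
#' @param epochs total training epochs.
#' @param batch_size segments per gradient step (1 in the reference
#'   protocol; larger values average gradients over consecutive segments).
#' @param prediction_steps rollout horizon: the decoder is re-grounded on
#'   the true state every `prediction_steps` frames within a window.
#' @param warmup_epochs initial epochs during which the latent sample is
#'   clamped to random half-on edge assignments (resampled per segment)
#'   and only the decoder trains, so the message MLPs learn the
#'   interaction law before the encoder starts gating edges (avoids the
#'   early-training pathology of switching off exactly the strongly
#'   coupled pairs whose messages are still uninformative).
#' @param output_variance variance of the Gaussian likelihood on the
#'   normalized features.
#' @param prior categorical prior over edge types, first entry = the
#'   non-interacting type. `NULL` means uniform. A sparsity-favoring prior
#'   (e.g. `c(0.9, 0.1)`) resolves the edge/non-edge label ambiguity that
#'   arises on centered coordinates, where the summed messages of a graph
#'   and of its complement carry the same information.
#' @param seed integer seed controlling initialization, segment order and
#'   Gumbel noise.
#' @param profile `"full"` or `"ci"`; presets for `epochs`.
#' @return A list of class `nri_config`.
#' @export
nri_config <- function(n_edge_types = 2L, hidden_dim = 64L,
                       gumbel_temperature = 0.5,
                       learning_rate = 5e-4, lr_decay_factor = 0.2,
                       lr_decay_every = 200L, epochs = NULL, batch_size = 1L,
                       prediction_steps = 10L, output_variance = 5e-5,
                       prior = NULL, warmup_epochs = NULL, seed = 1L,
                       profile = c("full", "ci")) {
  profile <- match.arg(profile)
  if (is.null(epochs)) epochs <- if (profile == "ci") 100L else 500L
  if (is.null(warmup_epochs)) warmup_epochs <- max(1L, round(epochs / 5))
  if (!is.null(prior)) {
    assert(length(prior) == n_edge_types && all(prior > 0),
           "prior must have one positive entry per edge type")
    prior <- prior / sum(prior)
  }
  cfg <- list(
    n_edge_types = as.integer(n_edge_types), hidden_dim = as.integer(hidden_dim),
    gumbel_temperature = gumbel_temperature, learning_rate = learning_rate,
    lr_decay_factor = lr_decay_factor, lr_decay_every = as.integer(lr_decay_every),
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    prediction_steps = as.integer(prediction_steps),
    output_variance = output_variance, prior = prior,
    warmup_epochs = as.integer(warmup_epochs),
    seed = as.integer(seed), profile = profile
  )
  assert(cfg$warmup_epochs >= 0L && cfg$warmup_epochs < cfg$epochs,
         "warmup_epochs must be in [0, epochs)")
  assert(cfg$n_edge_types >= 2L, "n_edge_types must be at least 2")
  assert(cfg$hidden_dim >= 1L && cfg$epochs >= 1L && cfg$batch_size >= 1L &&
           cfg$prediction_steps >= 1L, "all counts must be >= 1")
  assert(cfg$gumbel_temperature > 0, "gumbel_temperature must be positive")
  assert(cfg$lr_decay_factor > 0 && cfg$lr_decay_factor <= 1,
         "lr_decay_factor must be in (0, 1]")
  assert(cfg$output_variance > 0, "output_variance must be positive")
  class(cfg) <- "nri_config"
  cfg
}

# ---- primitives -----------------------------------------------------------

elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}

delu <- function(x) {
  neg <- x < 0
  e <- exp(x[neg])
  x[] <- 1
  x[neg] <- e
  x
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1, max)
  e <- exp(x)
  e / rowSums(e)
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

new_linear <- function(nin, nout) list(W = glorot(nin, nout), b = numeric(nout))

new_mlp <- function(nin, nhid, nout) {
  list(l1 = new_linear(nin, nhid), l2 = new_linear(nhid, nout))
}

# column-major bias add (b recycled down each column)
add_bias <- function(a, b) a + rep(b, each = nrow(a))

# Two-layer MLP with ELU after layer 1 and optionally after layer 2.
# Negative-region masks are cached so the backward pass applies the ELU
# derivative (1 for x > 0, elu(x) + 1 otherwise) by subset multiplication.
mlp_fwd <- function(p, x, act_out = TRUE) {
  h1 <- add_bias(x %*% p$l1$W, p$l1$b)
  neg1 <- h1 < 0
  h1[neg1] <- expm1(h1[neg1])
  out <- add_bias(h1 %*% p$l2$W, p$l2$b)
  neg2 <- NULL
  if (act_out) {
    neg2 <- out < 0
    out[neg2] <- expm1(out[neg2])
  }
  list(x = x, h1 = h1, neg1 = neg1, out = out, neg2 = neg2,
       act_out = act_out)
}

# Backward pass; returns grads for the two layers and the input gradient.
mlp_bwd <- function(p, cache, dout) {
  da2 <- dout
  if (cache$act_out) {
    da2[cache$neg2] <- da2[cache$neg2] * (cache$out[cache$neg2] + 1)
  }
  g2 <- list(W = crossprod(cache$h1, da2), b = colSums(da2))
  da1 <- da2 %*% t(p$l2$W)
  da1[cache$neg1] <- da1[cache$neg1] * (cache$h1[cache$neg1] + 1)
  g1 <- list(W = crossprod(cache$x, da1), b = colSums(da1))
  list(grad = list(l1 = g1, l2 = g2), dx = da1 %*% t(p$l1$W))
}

# Ordered node pairs (sender, receiver), excluding self pairs, sorted by
# sender then receiver. This ordering is the edge-row convention everywhere.
ordered_pairs <- function(n) {
  send <- rep(seq_len(n), each = n - 1L)
  recv <- unlist(lapply(seq_len(n), function(i) setdiff(seq_len(n), i)),
                 use.names = FALSE)
  list(send = send, recv = recv, n = as.integer(n))
}

#' Initialize an NRI model
#'
#' Builds the encoder (graph neural network over the fully connected node
#' graph: node embedding, node-to-edge, edge-to-node, node-to-edge rounds)
#' and the decoder (per-edge-type message MLPs plus an output MLP predicting
#' mean displacements). Weights are Glorot-initialized from the seeded RNG.
#'
#' @param n_nodes number of nodes (residues) the model operates on.
#' @param window frames per input segment.
#' @param n_channels feature channels per node (6: position + velocity).
#' @param config an [nri_config()].
#' @return A list of class `nri_model` with fields `params`, `pairs`,
#'   `config`, `n_nodes`, `window`, `n_channels`.
#' @export
nri_model <- function(n_nodes, window, n_channels = 6L, config = nri_config()) {
  H <- config$hidden_dim
  K <- config$n_edge_types
  C <- n_channels
  din <- window * C
  params <- list(
    enc = list(
      emb = new_mlp(din, H, H),
      e1 = new_mlp(2L * H, H, H),
      node = new_mlp(H, H, H),
      out = new_mlp(2L * H, H, K)
    ),
    dec = list(
      msg = lapply(seq_len(K - 1L), function(k) new_mlp(2L * C, H, H)),
      out = new_mlp(C + H, H, C)
    )
  )
  # near-identity initial dynamics: small output weights keep early
  # multi-step rollouts from amplifying
  params$dec$out$l2$W <- params$dec$out$l2$W * 0.1
  structure(
    list(params = params, pairs = ordered_pairs(n_nodes), config = config,
         n_nodes = as.integer(n_nodes), window = as.integer(window),
         n_channels = as.integer(C)),
    class = "nri_model"
  )
}

#' @export
print.nri_model <- function(x, ...) {
  cat(sprintf(
    "<nri_model> %d nodes, window %d, hidden %d, %d edge types (%s profile)\n",
    x$n_nodes, x$window, x$config$hidden_dim, x$config$n_edge_types,
    x$config$profile))
  invisible(x)
}

# Flatten a window x nodes x channels segment into the encoder input matrix
# (nodes x (window * channels)).
segment_to_matrix <- function(segment, n_nodes) {
  assert(length(dim(segment)) == 3L, "segment must be a 3-d array")
  t(apply(segment, 2, identity))  # nodes x (window*channels), column-major
}

enc_forward <- function(params, X, pairs) {
  n <- pairs$n
  emb <- mlp_fwd(params$enc$emb, X)
  ein <- cbind(emb$out[pairs$send, , drop = FALSE],
               emb$out[pairs$recv, , drop = FALSE])
  e1 <- mlp_fwd(params$enc$e1, ein)
  agg <- rowsum(e1$out, pairs$recv) / (n - 1L)
  dimnames(agg) <- NULL
  node <- mlp_fwd(params$enc$node, agg)
  oin <- cbind(node$out[pairs$send, , drop = FALSE],
               node$out[pairs$recv, , drop = FALSE])
  out <- mlp_fwd(params$enc$out, oin, act_out = FALSE)
  list(emb = emb, e1 = e1, node = node, out = out, logits = out$out)
}

enc_backward <- function(params, cache, pairs, dlogits) {
  n <- pairs$n
  H <- ncol(cache$node$out)
  bo <- mlp_bwd(params$enc$out, cache$out, dlogits)
  dnode_out <- rowsum(bo$dx[, seq_len(H), drop = FALSE], pairs$send) +
    rowsum(bo$dx[, H + seq_len(H), drop = FALSE], pairs$recv)
  bn <- mlp_bwd(params$enc$node, cache$node, dnode_out)
  de1 <- bn$dx[pairs$recv, , drop = FALSE] / (n - 1L)
  be <- mlp_bwd(params$enc$e1, cache$e1, de1)
  demb <- rowsum(be$dx[, seq_len(H), drop = FALSE], pairs$send) +
    rowsum(be$dx[, H + seq_len(H), drop = FALSE], pairs$recv)
  bm <- mlp_bwd(params$enc$emb, cache$emb, demb)
  list(enc = list(emb = bm$grad, e1 = be$grad, node = bn$grad, out = bo$grad))
}

#' Encoder pass: edge-type logits for one segment
#'
#' Runs the variational encoder on a `window x nodes x channels` feature
#' segment and returns per-ordered-pair edge-type logits. The pass is pure:
#' repeated calls with the same model and segment give identical results.
#'
#' @param model an [nri_model()].
#' @param segment array `window x nodes x channels`.
#' @return Numeric matrix `(n_nodes * (n_nodes - 1)) x n_edge_types` of
#'   logits; rows follow the ordered-pair convention (sorted by sender,
#'   then receiver).
#' @export
nri_encode <- function(model, segment) {
  d <- dim(segment)
  assert(length(d) == 3L && d[2] == model$n_nodes,
         "segment node count (%d) does not match model (%d)",
         d[2], model$n_nodes)
  assert(d[1] >= 2L, "segment must have at least 2 frames")
  X <- segment_to_matrix(segment, model$n_nodes)
  logits <- enc_forward(model$params, X, model$pairs)$logits
  assert(all(is.finite(logits)), "encoder produced non-finite logits")
  logits
}

#' Gumbel-softmax (concrete) sample of latent edge types
#'
#' Draws a relaxed one-hot sample per ordered pair. With `hard = TRUE` the
#' sample is quantized to an exact one-hot vector (straight-through: the
#' soft sample is attached as attribute `"soft"` and is the value whose
#' gradient the training loop uses).
#'
#' @param logits pair x edge-type logit matrix.
#' @param temperature positive relaxation temperature.
#' @param seed optional integer seed; when NULL the current RNG stream is
#'   used.
#' @param hard quantize to one-hot?
#' @return Matrix of the same shape as `logits`, rows summing to 1.
#' @export
gumbel_softmax_sample <- function(logits, temperature = 0.5, seed = NULL,
                                  hard = FALSE) {
  assert(temperature > 0, "temperature must be positive")
  draw <- function() {
    u <- matrix(stats::runif(length(logits)), nrow(logits), ncol(logits))
    g <- -log(-log(u))
    softmax_rows((logits + g) / temperature)
  }
  y <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (hard) {
    hardy <- matrix(0, nrow(y), ncol(y))
    hardy[cbind(seq_len(nrow(y)), max.col(y, ties.method = "first"))] <- 1
    attr(hardy, "soft") <- y
    return(hardy)
  }
  y
}

# Batched decoder step over B stacked copies of the node set. `z_rep` has
# one row per (chunk, pair), matching send_b/recv_b row order.
dec_forward_step <- function(params, S, z_rep, send_b, recv_b) {
  C <- ncol(S)
  pin <- cbind(S[send_b, , drop = FALSE], S[recv_b, , drop = FALSE])
  msgs <- vector("list", length(params$dec$msg))
  msg_sum <- NULL
  for (k in seq_along(params$dec$msg)) {
    mk <- mlp_fwd(params$dec$msg[[k]], pin)
    contrib <- mk$out * z_rep[, k + 1L]
    msg_sum <- if (is.null(msg_sum)) contrib else msg_sum + contrib
    msgs[[k]] <- mk
  }
  agg <- rowsum(msg_sum, recv_b)
  dimnames(agg) <- NULL
  oin <- cbind(S, agg)
  out <- mlp_fwd(params$dec$out, oin, act_out = FALSE)
  list(S = S, pin = pin, msgs = msgs, oin = oin, out = out,
       S_next = S + out$out)
}

dec_backward_step <- function(params, cache, z_rep, send_b, recv_b,
                              pair_rep, dS_next) {
  C <- ncol(cache$S)
  H <- ncol(cache$oin) - C
  bo <- mlp_bwd(params$dec$out, cache$out, dS_next)
  dS <- dS_next + bo$dx[, seq_len(C), drop = FALSE]
  dagg <- bo$dx[, C + seq_len(H), drop = FALSE]
  dmsg <- dagg[recv_b, , drop = FALSE]
  dpin <- NULL
  msg_grads <- vector("list", length(params$dec$msg))
  dz <- matrix(0, max(pair_rep), length(params$dec$msg) + 1L)
  for (k in seq_along(params$dec$msg)) {
    mk <- cache$msgs[[k]]
    dz[, k + 1L] <- rowsum(rowSums(dmsg * mk$out), pair_rep)
    dmk <- dmsg * z_rep[, k + 1L]
    bk <- mlp_bwd(params$dec$msg[[k]], mk, dmk)
    msg_grads[[k]] <- bk$grad
    dpin <- if (is.null(dpin)) bk$dx else dpin + bk$dx
  }
  dS <- dS + rowsum(dpin[, seq_len(C), drop = FALSE], send_b) +
    rowsum(dpin[, C + seq_len(C), drop = FALSE], recv_b)
  list(grad = list(dec = list(msg = msg_grads, out = bo$grad)),
       dS = dS, dz = dz)
}

#' Single decoder prediction step
#'
#' Predicts the node states at the next frame from the current states and a
#' latent edge-type assignment. Edge type 1 is non-interacting: its message
#' channel is hard-wired to zero, so a node's prediction is independent of
#' any node connected to it only by type-1 edges.
#'
#' @param model an [nri_model()].
#' @param state `n_nodes x n_channels` matrix of current node features.
#' @param edge_sample pair x edge-type matrix (e.g. a
#'   [gumbel_softmax_sample()] or the encoder posterior).
#' @return `n_nodes x n_channels` matrix of predicted next states.
#' @export
nri_decode_step <- function(model, state, edge_sample) {
  state <- as.matrix(state)
  assert(nrow(state) == model$n_nodes, "state row count must equal n_nodes")
  assert(nrow(edge_sample) == length(model$pairs$send),
         "edge_sample must have one row per ordered pair")
  assert(all(vapply(tree_leaves(model$params), function(m) all(is.finite(m)),
                    TRUE)), "model parameters contain non-finite values")
  dec_forward_step(model$params, state, edge_sample,
                   model$pairs$send, model$pairs$recv)$S_next
}

#' ELBO-style training loss
#'
#' Gaussian negative log-likelihood of the predicted segments (proportional
#' to MSE / (2 sigma^2), averaged per predicted entry) plus the mean KL
#' divergence of the per-pair edge posterior from the uniform categorical
#' prior. Both terms are reported separately.
#'
#' @param predicted,true arrays (or vectors) of equal shape.
#' @param edge_posterior pair x edge-type probability matrix.
#' @param output_variance Gaussian likelihood variance.
#' @param prior edge-type prior (default uniform).
#' @return list with `recon`, `kl` and `total`.
#' @export
nri_elbo <- function(predicted, true, edge_posterior, output_variance = 5e-5,
                     prior = NULL) {
  assert(length(predicted) == length(true), "prediction/target shape mismatch")
  recon <- mean((predicted - true)^2) / (2 * output_variance)
  kl <- mean(kl_rows(edge_posterior, prior))
  list(recon = recon, kl = kl, total = recon + kl)
}

# Per-row KL(q || prior) for a row-stochastic matrix; NULL prior = uniform.
kl_rows <- function(q, prior = NULL) {
  k <- ncol(q)
  logp <- if (is.null(prior)) rep(-log(k), k) else log(prior)
  qs <- pmax(q, 1e-16)
  rowSums(qs * (log(qs) - rep(logp, each = nrow(q))))
}

#' Latent interaction graph
#'
#' Per-ordered-pair categorical edge-type distribution inferred by the NRI
#' encoder, averaged over segments (and, via [consensus_graph()], over
#' replicate trajectories). The interaction probability of a pair is defined
#' as 1 minus the probability of the non-interacting type.
#'
#' @param probs pair x edge-type probability matrix (ordered-pair row
#'   convention); rows must sum to 1 within 1e-6.
#' @param n_nodes node count.
#' @param residues residue number of each node (defaults to 1..n).
#' @param provenance free-form list (replicate ids, config hash, segment
#'   count).
#' @return An object of class `LatentInteractionGraph`.
#' @export
latent_interaction_graph <- function(probs, n_nodes, residues = NULL,
                                     provenance = list()) {
  pairs <- ordered_pairs(n_nodes)
  assert(nrow(probs) == length(pairs$send),
         "probs must have one row per ordered pair (%d), got %d",
         length(pairs$send), nrow(probs))
  assert(all(probs >= -1e-9), "edge-type probabilities must be non-negative")
  assert(all(abs(rowSums(probs) - 1) < 1e-6),
         "edge-type probabilities must sum to 1 per pair")
  structure(
    list(n_nodes = as.integer(n_nodes),
         residues = as.integer(residues %||% seq_len(n_nodes)),
         send = pairs$send, recv = pairs$recv,
         probs = probs, provenance = provenance),
    class = "LatentInteractionGraph"
  )
}

#' @export
print.LatentInteractionGraph <- function(x, ...) {
  cat(sprintf("<LatentInteractionGraph> %d nodes, %d ordered pairs, %d edge types\n",
              x$n_nodes, length(x$send), ncol(x$probs)))
  invisible(x)
}

#' Interaction-probability matrix of a latent graph
#'
#' @param graph a [latent_interaction_graph()].
#' @return `n x n` matrix with entry (i, j) = 1 - P(non-interacting) for the
#'   ordered pair i -> j; the diagonal is 0.
#' @export
interaction_matrix <- function(graph) {
  n <- graph$n_nodes
  m <- matrix(0, n, n, dimnames = list(graph$residues, graph$residues))
  m[cbind(graph$send, graph$recv)] <- 1 - graph$probs[, 1]
  m
}

#' Planted-edge recovery score (AUROC)
#'
#' Area under the ROC curve of the per-pair interaction probabilities
#' against a planted undirected edge set, computed by the Mann-Whitney
#' rank statistic. Each ordered pair is labelled positive when its
#' unordered pair is a planted edge.
#'
#' @param graph a [latent_interaction_graph()] (or an interaction-
#'   probability matrix).
#' @param edges two-column matrix of planted unordered edges, in node
#'   indices 1..n matching the graph's node order.
#' @return AUROC in `[0, 1]`; 0.5 is chance level.
#' @export
edge_recovery_auroc <- function(graph, edges) {
  m <- if (inherits(graph, "LatentInteractionGraph")) {
    interaction_matrix(graph)
  } else {
    as.matrix(graph)
  }
  n <- nrow(m)
  e <- canonical_edges(edges)
  adj <- matrix(FALSE, n, n)
  adj[e] <- TRUE
  adj <- adj | t(adj)
  off <- row(m) != col(m)
  scores <- m[off]
  labels <- adj[off]
  n1 <- sum(labels)
  n0 <- sum(!labels)
  assert(n1 > 0 && n0 > 0, "need both planted and absent pairs for AUROC")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average latent graphs across replicates
#'
#' Element-wise mean of the per-pair edge-type distributions of several
#' latent interaction graphs inferred from replicate trajectories.
#'
#' @param graphs list of [latent_interaction_graph()] objects with identical
#'   node and edge-type counts.
#' @return A consensus [latent_interaction_graph()].
#' @export
consensus_graph <- function(graphs) {
  assert(length(graphs) >= 1L, "need at least one graph")
  n <- graphs[[1]]$n_nodes
  k <- ncol(graphs[[1]]$probs)
  for (g in graphs) {
    assert(inherits(g, "LatentInteractionGraph"), "inputs must be latent graphs")
    assert(g$n_nodes == n && ncol(g$probs) == k,
           "graph shape mismatch: %d nodes x %d types vs %d x %d",
           g$n_nodes, ncol(g$probs), n, k)
  }
  probs <- Reduce(`+`, lapply(graphs, `[[`, "probs")) / length(graphs)
  latent_interaction_graph(
    probs, n, residues = graphs[[1]]$residues,
    provenance = list(
      replicates = unlist(lapply(graphs, function(g) g$provenance$replicates)),
      n_graphs = length(graphs)
    )
  )
}
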