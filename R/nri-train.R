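# NRI training: hand-derived backpropagation through the decoder rollout,
# the Gumbel-softmax relaxation and the GNN encoder, optimized with Adam.
# A finite-difference gradient check in the test suite guards the math.

tree_zero <- function(params) tree_map(function(x) x * 0, params)
tree_add <- function(a, b) tree_map(`+`, a, b)
tree_scale <- function(a, s) tree_map(function(x) x * s, a)

adam_init <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- tree_map(function(p, m, v) p - lr * (m / bc1) / (sqrt(v / bc2) + eps),
                     params, state$m, state$v)
  list(params = params, state = state)
}

# Stack chunk starting states / targets into a (B * n_nodes) x C matrix with
# chunk-major row order.
stack_frames <- function(seg, frames) {
  arr <- seg[frames, , , drop = FALSE]
  matrix(aperm(arr, c(2, 1, 3)), length(frames) * dim(seg)[2], dim(seg)[3])
}

# Precompute everything about one segment that does not depend on the
# parameters: encoder input, stacked chunk starts/targets, batched pair
# indices.
make_segment_prep <- function(seg, pairs, prediction_steps) {
  n <- pairs$n
  P <- length(pairs$send)
  tt <- dim(seg)[1]
  C <- dim(seg)[3]
  M <- min(prediction_steps, tt - 1L)
  B <- max(1L, (tt - 1L) %/% M)
  starts <- 1L + (seq_len(B) - 1L) * M
  send_b <- rep((seq_len(B) - 1L) * n, each = P) + pairs$send
  recv_b <- rep((seq_len(B) - 1L) * n, each = P) + pairs$recv
  pair_rep <- rep(seq_len(P), times = B)
  list(
    X = segment_to_matrix(seg, n),
    S0 = stack_frames(seg, starts),
    targets = lapply(seq_len(M), function(m) stack_frames(seg, starts + m)),
    send_b = send_b, recv_b = recv_b, pair_rep = pair_rep,
    send0 = pairs$send - 1L, recv0 = pairs$recv - 1L,
    send_b0 = send_b - 1L, recv_b0 = recv_b - 1L, pair_rep0 = pair_rep - 1L,
    M = M, B = B, n_entries = as.numeric(B) * n * C * M
  )
}

# Forward + backward for one segment; returns loss terms and the full
# parameter gradient tree. With `z_override` the latent sample is clamped
# (decoder warm-up): the encoder is skipped and only decoder gradients are
# produced. Dispatches to the compiled kernel; `nri_segment_grad_r` is the
# pure-R reference implementation with identical semantics.
nri_segment_grad <- function(params, pairs, prep, cfg, gumbel_noise = NULL,
                             z_override = NULL) {
  P <- length(pairs$send)
  K <- cfg$n_edge_types
  warmup <- !is.null(z_override)
  if (!warmup && is.null(gumbel_noise)) {
    u <- matrix(stats::runif(P * K), P, K)
    gumbel_noise <- -log(-log(u))
  }
  log_prior <- if (is.null(cfg$prior)) rep(-log(K), K) else log(cfg$prior)
  nri_segment_grad_cpp(
    params, prep$X, prep$S0, prep$targets,
    prep$send0, prep$recv0, prep$send_b0, prep$recv_b0, prep$pair_rep0,
    if (warmup) matrix(0, P, K) else gumbel_noise,
    if (warmup) z_override else matrix(0, P, K),
    warmup, cfg$gumbel_temperature, cfg$output_variance, log_prior,
    prep$n_entries
  )
}

nri_segment_grad_r <- function(params, pairs, prep, cfg, gumbel_noise = NULL,
                               z_override = NULL) {
  n <- pairs$n
  P <- length(pairs$send)
  K <- cfg$n_edge_types
  tau <- cfg$gumbel_temperature
  sigma2 <- cfg$output_variance
  M <- prep$M

  warmup <- !is.null(z_override)
  if (warmup) {
    z <- z_override
    q <- z
    ec <- NULL
  } else {
    ec <- enc_forward(params, prep$X, pairs)
    logits <- ec$logits
    if (any(!is.finite(logits))) return(list(diverged = TRUE))
    q <- softmax_rows(logits)
    if (is.null(gumbel_noise)) {
      u <- matrix(stats::runif(P * K), P, K)
      gumbel_noise <- -log(-log(u))
    }
    z <- softmax_rows((logits + gumbel_noise) / tau)
  }

  send_b <- prep$send_b
  recv_b <- prep$recv_b
  pair_rep <- prep$pair_rep
  z_rep <- z[pair_rep, , drop = FALSE]

  S <- prep$S0
  caches <- vector("list", M)
  targets <- prep$targets
  preds <- vector("list", M)
  for (m in seq_len(M)) {
    caches[[m]] <- dec_forward_step(params, S, z_rep, send_b, recv_b)
    preds[[m]] <- caches[[m]]$S_next
    S <- preds[[m]]
  }
  n_entries <- prep$n_entries
  targets <- prep$targets
  sse <- sum(vapply(seq_len(M),
                    function(m) sum((preds[[m]] - targets[[m]])^2), 0))
  recon <- sse / (2 * sigma2 * n_entries)
  kl_row <- if (warmup) 0 else kl_rows(q, cfg$prior)
  kl <- mean(kl_row)
  if (!is.finite(recon + kl)) return(list(diverged = TRUE))

  # backward through the rollout
  grads <- NULL
  dz_total <- matrix(0, P, K)
  dS <- matrix(0, nrow(S), ncol(S))
  for (m in rev(seq_len(M))) {
    dS_next <- (preds[[m]] - targets[[m]]) / (sigma2 * n_entries) + dS
    bk <- dec_backward_step(params, caches[[m]], z_rep, send_b, recv_b,
                            pair_rep, dS_next)
    grads <- if (is.null(grads)) bk$grad else tree_add(grads, bk$grad)
    dz_total <- dz_total + bk$dz
    dS <- bk$dS
  }

  if (warmup) {
    enc <- tree_zero(params$enc)
  } else {
    # Gumbel-softmax chain: z = softmax((logits + g) / tau)
    dlogits_z <- z * (dz_total - rowSums(z * dz_total)) / tau
    # KL term: kl = mean_p sum_k q (log q - log prior)
    logp <- if (is.null(cfg$prior)) rep(-log(K), K) else log(cfg$prior)
    dlogits_kl <- q * ((log(pmax(q, 1e-16)) - rep(logp, each = P)) - kl_row) / P
    enc <- enc_backward(params, ec, pairs, dlogits_z + dlogits_kl)$enc
  }

  list(diverged = FALSE,
       grads = list(enc = enc, dec = grads$dec),
       recon = recon, kl = kl, total = recon + kl, q = q)
}

#' Train an NRI model on trajectory segments
#'
#' Fits the variational encoder/decoder with Adam under the reference
#' schedule (initial learning rate from the config, decayed by
#' `lr_decay_factor` every `lr_decay_every` epochs, `batch_size` segments
#' per update). Per-epoch reconstruction and KL losses are recorded. After
#' training, the encoder posterior is computed for every segment and
#' averaged into the returned [latent_interaction_graph()]. Given the same
#' seed and inputs the result is deterministic.
#'
#' @param segments list of `window x nodes x channels` arrays (e.g. from
#'   [window_segments()] applied to [compute_features()] values), or a
#'   `FeatureTensor` together with `window`/`stride`.
#' @param config an [nri_config()].
#' @param window,stride segmentation parameters, used only when `segments`
#'   is a `FeatureTensor`.
#' @param residues residue numbers of the nodes (defaults from the feature
#'   tensor when available).
#' @param replicate_id optional label recorded in the graph provenance.
#' @param canonicalize resolve the latent edge-type label symmetry (the
#'   two-type model is invariant under swapping which type passes
#'   messages) by requiring interaction probability to anti-correlate with
#'   the time-averaged inter-node distance, the physical expectation for
#'   elastic networks and residue contact graphs. Only applies when
#'   `n_edge_types == 2`; whether a swap occurred is recorded in the graph
#'   provenance.
#' @param verbose print the loss every 20 epochs?
#' @return An object of class `nri_fit`: list with `model`, `graph`,
#'   `loss_history` (data frame epoch/recon/kl/total/lr) and `config`.
#' @export
train_nri <- function(segments, config = nri_config(), window = 50L,
                      stride = 100L, residues = NULL, replicate_id = NULL,
                      canonicalize = TRUE, verbose = FALSE) {
  if (inherits(segments, "FeatureTensor")) {
    residues <- residues %||% segments$residues
    segments <- window_segments(segments$values, window, stride)
  }
  assert(is.list(segments) && length(segments) >= 1L,
         "segments must be a non-empty list of window x nodes x channels arrays")
  d <- dim(segments[[1]])
  n <- d[2]
  C <- d[3]
  tt <- d[1]
  n_seg <- length(segments)
  pairs <- ordered_pairs(n)

  history <- data.frame(epoch = integer(0), recon = numeric(0),
                        kl = numeric(0), total = numeric(0), lr = numeric(0))
  fit <- with_seed(config$seed, {
    model <- nri_model(n, tt, C, config)
    params <- model$params
    preps <- lapply(segments, make_segment_prep, pairs = pairs,
                    prediction_steps = config$prediction_steps)
    opt <- adam_init(params)
    P <- length(pairs$send)
    K <- config$n_edge_types
    # warm-up clamp: random half of the pairs interact, resampled per
    # segment, so message functions learn per-pair content rather than a
    # collective mean-field summary
    draw_z_warm <- function() {
      on <- stats::runif(P) < 0.5
      cbind(as.numeric(!on), matrix(as.numeric(on) / (K - 1L), P, K - 1L))
    }
    for (epoch in seq_len(config$epochs)) {
      lr <- config$learning_rate *
        config$lr_decay_factor^((epoch - 1L) %/% config$lr_decay_every)
      in_warmup <- epoch <= config$warmup_epochs
      perm <- sample.int(n_seg)
      ep_recon <- ep_kl <- 0
      i <- 1L
      while (i <= n_seg) {
        idx <- perm[i:min(i + config$batch_size - 1L, n_seg)]
        batch_grads <- NULL
        for (s in idx) {
          res <- nri_segment_grad(params, pairs, preps[[s]], config,
                                  z_override = if (in_warmup) draw_z_warm() else NULL)
          if (isTRUE(res$diverged)) {
            stopf("NRI training diverged (non-finite loss) at epoch %d, lr %g",
                  epoch, lr)
          }
          ep_recon <- ep_recon + res$recon
          ep_kl <- ep_kl + res$kl
          batch_grads <- if (is.null(batch_grads)) res$grads else
            tree_add(batch_grads, res$grads)
        }
        if (length(idx) > 1L) {
          batch_grads <- tree_scale(batch_grads, 1 / length(idx))
        }
        upd <- adam_step(params, batch_grads, opt, lr)
        params <- upd$params
        opt <- upd$state
        i <- i + config$batch_size
      }
      history[nrow(history) + 1L, ] <-
        list(epoch, ep_recon / n_seg, ep_kl / n_seg,
             (ep_recon + ep_kl) / n_seg, lr)
      if (verbose && (epoch %% 20L == 0L || epoch == 1L)) {
        message(sprintf("epoch %4d  recon %.4f  kl %.4f  lr %g",
                        epoch, ep_recon / n_seg, ep_kl / n_seg, lr))
      }
    }
    model$params <- params
    model
  })

  probs <- Reduce(`+`, lapply(segments, function(s) {
    softmax_rows(nri_encode(fit, s))
  })) / n_seg
  flipped <- FALSE
  if (canonicalize && config$n_edge_types == 2L) {
    pd <- mean_pair_distance(segments, pairs)
    r <- suppressWarnings(stats::cor(1 - probs[, 1], pd))
    if (is.finite(r) && r > 0) {
      probs <- probs[, c(2L, 1L), drop = FALSE]
      flipped <- TRUE
    }
  }
  graph <- latent_interaction_graph(
    probs, n, residues = residues,
    provenance = list(replicates = replicate_id, n_segments = n_seg,
                      label_swap = flipped,
                      config_hash = rlang::hash(unclass(config)))
  )
  structure(list(model = fit, graph = graph, loss_history = history,
                 config = config),
            class = "nri_fit")
}

#' @export
print.nri_fit <- function(x, ...) {
  n <- nrow(x$loss_history)
  cat(sprintf("<nri_fit> %d epochs; final loss %.4f (recon %.4f, kl %.4f)\n",
              n, x$loss_history$total[n], x$loss_history$recon[n],
              x$loss_history$kl[n]))
  invisible(x)
}

# Time-averaged inter-node distance per ordered pair, from the position
# channels of the feature segments (the normalization scale cancels in the
# correlation it is used for).
mean_pair_distance <- function(segments, pairs) {
  acc <- numeric(length(pairs$send))
  nT <- 0L
  for (seg in segments) {
    pos <- seg[, , 1:3, drop = FALSE]
    for (tt in seq_len(dim(pos)[1])) {
      xy <- pos[tt, , ]
      acc <- acc + sqrt(rowSums((xy[pairs$send, , drop = FALSE] -
                                 xy[pairs$recv, , drop = FALSE])^2))
    }
    nT <- nT + dim(pos)[1]
  }
  acc / nT
}

#' Reverse-sampling consistency check
#'
#' Splits the residues into the spatially uniform half and its complement,
#' trains an independent NRI model on each half, computes region-level
#' cross-strength matrices from both latent graphs, and returns their
#' Spearman rank correlation. A high score indicates that the sparse
#' sampling preserves the region-level communication structure.
#'
#' @param traj a superposed [trajectory()].
#' @param fraction fraction of residues in the primary half (default 0.5).
#' @param config an [nri_config()] used for both trainings.
#' @param regions named list of residue-number vectors (or a
#'   [region_set()]).
#' @param window,stride segmentation parameters.
#' @return list with `score` (Spearman correlation, `NA` when either matrix
#'   is constant), `selected_matrix`, `complement_matrix`, `selection` and
#'   the two `nri_fit` objects.
#' @export
reverse_sampling_check <- function(traj, fraction = 0.5,
                                   config = nri_config(profile = "ci"),
                                   regions, window = 50L, stride = 100L) {
  if (inherits(regions, "RegionSet")) regions <- regions$regions
  sel <- sparse_sample(traj, fraction, seed = config$seed)
  for (nm in names(regions)) {
    in_sel <- intersect(regions[[nm]], sel$selected)
    in_comp <- intersect(regions[[nm]], sel$complement)
    if (length(in_sel) == 0L || length(in_comp) == 0L) {
      stopf("region '%s' has no residues in the %s half", nm,
            if (length(in_sel) == 0L) "selected" else "complement")
    }
  }
  halves <- list(selected = sel, complement = reverse_selection(sel))
  fits <- lapply(halves, function(h) {
    feats <- compute_features(traj, h)
    train_nri(feats, config, window = window, stride = stride,
              replicate_id = h$mode)
  })
  mats <- lapply(fits, function(f) {
    cross_region_strength(f$graph, regions)
  })
  a <- as.vector(mats$selected)
  b <- as.vector(mats$complement)
  ok <- is.finite(a) & is.finite(b)  # within-region means can be undefined
                                     # when a half holds a single residue
  score <- if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) {
    message("reverse-sampling check: degenerate constant matrix, score undefined")
    NA_real_
  } else {
    stats::cor(a[ok], b[ok], method = "spearman")
  }
  list(score = score, selected_matrix = mats$selected,
       complement_matrix = mats$complement, selection = sel, fits = fits)
}
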