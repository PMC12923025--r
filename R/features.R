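#' Spatially uniform residue subsampling
#'
#' Selects a fraction of residues by farthest-point sampling on the
#' time-averaged Calpha coordinates: the first residue is drawn at random
#' (seeded), then residues are added greedily, each maximizing its distance
#' to the already-selected set. The complement is retained as the
#' reverse-sampling set, so the two halves partition the residues.
#'
#' @param traj a superposed [trajectory()].
#' @param fraction fraction of residues to select, in (0, 1].
#' @param seed integer seed for the starting residue.
#' @return An object of class `ResidueSelection` with fields `selected`,
#'   `complement` (both sorted ascending), `mode` and `fraction`.
#' @export
sparse_sample <- function(traj, fraction = 0.5, seed = 1L) {
  assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  mean_ca <- ca_coords(traj)
  residues <- sort(unique(traj$atom_meta$resno))
  assert(nrow(mean_ca) == length(residues),
         "trajectory has no Calpha-like atom for every residue")
  n <- length(residues)
  n_sel <- ceiling(fraction * n)
  sel <- integer(n_sel)
  with_seed(seed, {
    sel[1] <- sample.int(n, 1L)
  })
  if (n_sel > 1L) {
    mind <- sqrt(rowSums(sweep(mean_ca, 2, mean_ca[sel[1], ])^2))
    for (i in 2:n_sel) {
      cand <- which.max(mind)  # ties: lowest index (which.max convention)
      sel[i] <- cand
      mind <- pmin(mind, sqrt(rowSums(sweep(mean_ca, 2, mean_ca[cand, ])^2)))
    }
  }
  residue_selection(selected = residues[sort(sel)],
                    complement = residues[sort(setdiff(seq_len(n), sel))],
                    mode = "uniform", fraction = fraction)
}

residue_selection <- function(selected, complement, mode, fraction) {
  assert(length(intersect(selected, complement)) == 0L,
         "selected and complement residues must be disjoint")
  structure(list(selected = as.integer(selected),
                 complement = as.integer(complement),
                 mode = mode, fraction = fraction),
            class = "ResidueSelection")
}

#' Swap a residue selection with its complement
#'
#' Returns the reverse-sampling counterpart of a [sparse_sample()] result:
#' the complement becomes the selected set.
#'
#' @param selection a `ResidueSelection`.
#' @return A `ResidueSelection` with mode `"reverse"`.
#' @export
reverse_selection <- function(selection) {
  residue_selection(selected = selection$complement,
                    complement = selection$selected,
                    mode = "reverse", fraction = 1 - selection$fraction)
}

#' @export
print.ResidueSelection <- function(x, ...) {
  cat(sprintf("<ResidueSelection:%s> %d selected / %d complement\n",
              x$mode, length(x$selected), length(x$complement)))
  invisible(x)
}

#' Segment a per-frame array into overlapping time windows
#'
#' Windows start at frames `1, 1 + stride, 1 + 2 stride, ...` and each
#' contains exactly `window` frames; windows that would run past the end are
#' dropped, giving `floor((n_frames - window) / stride) + 1` segments.
#'
#' @param x an array whose first dimension indexes frames (e.g. the `values`
#'   field of [compute_features()]), or a vector.
#' @param window frames per segment (>= 2).
#' @param stride frame offset between segment starts (>= 1).
#' @return A list of segments, each a slice of `x` with `window` frames.
#' @export
window_segments <- function(x, window, stride) {
  assert(window >= 2L, "window must be at least 2")
  assert(stride >= 1L, "stride must be at least 1")
  nf <- if (is.array(x)) dim(x)[1] else length(x)
  assert(nf >= window, "need at least %d frames, got %d", window, nf)
  starts <- seq(1L, nf - window + 1L, by = stride)
  lapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    if (is.array(x)) {
      nd <- length(dim(x))
      do.call(`[`, c(list(x, idx), rep(list(quote(expr = )), nd - 1L),
                     list(drop = FALSE)))
    } else {
      x[idx]
    }
  })
}

#' Position and velocity features for relational inference
#'
#' For each selected residue, extracts the Calpha positions and
#' finite-difference velocities (saved-frame trajectories carry no
#' velocities). The default is the backward difference
#' `v_t = (x_t - x_{t-1}) / dt` (the first frame repeats the second frame's
#' velocity), so that the feature vector at time t contains no information
#' about frames after t; a forward difference
#' `v_t = (x_{t+1} - x_t) / dt` is also available but leaks the next frame
#' into the current state, which short-circuits one-step dynamics
#' prediction. Positions are centered on the centroid of the time-averaged
#' selected coordinates; the position channel group and the velocity channel
#' group are then each scaled so that their maximum absolute value is
#' exactly 1. The centering offset and both scale factors are retained so
#' the transformation can be inverted.
#'
#' @param traj a superposed [trajectory()] with at least 2 frames.
#' @param selection a `ResidueSelection`, an integer vector of residue
#'   numbers, or NULL for all residues.
#' @param velocity `"backward"` (default) or `"forward"` finite
#'   differences.
#' @return An object of class `FeatureTensor`: list with `values`
#'   (`frames x nodes x 6` array, channels x,y,z position then x,y,z
#'   velocity), `norm_constants` (center, pos_scale, vel_scale, dt) and
#'   `residues` (the residue number of each node column).
#' @export
compute_features <- function(traj, selection = NULL,
                             velocity = c("backward", "forward")) {
  velocity <- match.arg(velocity)
  assert(n_frames(traj) >= 2L,
         "cannot form velocity features from a single-frame trajectory")
  residues <- if (is.null(selection)) {
    sort(unique(traj$atom_meta$resno))
  } else if (inherits(selection, "ResidueSelection")) {
    selection$selected
  } else {
    sort(as.integer(selection))
  }
  assert(length(residues) > 0L, "empty residue selection")
  idx <- ca_indices(traj)
  res_of_idx <- traj$atom_meta$resno[idx]
  cols <- match(residues, res_of_idx)
  assert(!anyNA(cols), "selection contains residues absent from the trajectory")
  pos <- traj$coords[, idx[cols], , drop = FALSE]  # T x N x 3

  dt <- if (n_frames(traj) > 1) diff(traj$times)[1] else 1
  vel <- pos
  tmax <- dim(pos)[1]
  if (velocity == "forward") {
    vel[-tmax, , ] <- (pos[-1, , , drop = FALSE] -
                         pos[-tmax, , , drop = FALSE]) / dt
    vel[tmax, , ] <- vel[tmax - 1L, , ]
  } else {
    vel[-1, , ] <- (pos[-1, , , drop = FALSE] -
                      pos[-tmax, , , drop = FALSE]) / dt
    vel[1, , ] <- vel[2, , ]
  }

  center <- colMeans(apply(pos, c(2, 3), mean))  # centroid of mean structure
  pos <- sweep(pos, 3, center)
  pos_scale <- max(abs(pos))
  vel_scale <- max(abs(vel))
  if (pos_scale == 0) pos_scale <- 1
  if (vel_scale == 0) vel_scale <- 1

  values <- array(0, c(tmax, length(residues), 6L))
  values[, , 1:3] <- pos / pos_scale
  values[, , 4:6] <- vel / vel_scale
  structure(
    list(values = values,
         norm_constants = list(center = center, pos_scale = pos_scale,
                               vel_scale = vel_scale, dt = dt),
         residues = residues),
    class = "FeatureTensor"
  )
}

#' Invert feature normalization
#'
#' Recovers positions (nm) and velocities (nm/ps) from a [compute_features()]
#' tensor.
#'
#' @param features a `FeatureTensor`.
#' @return list with arrays `positions` and `velocities`.
#' @export
denormalize_features <- function(features) {
  nc <- features$norm_constants
  pos <- features$values[, , 1:3, drop = FALSE] * nc$pos_scale
  pos <- sweep(pos, 3, nc$center, `+`)
  vel <- features$values[, , 4:6, drop = FALSE] * nc$vel_scale
  list(positions = pos, velocities = vel)
}
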