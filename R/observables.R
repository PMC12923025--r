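# Structural and dynamic observables computed directly from trajectories.
# Conventions: coordinates in nm, 1-based residue numbering, heavy atoms are
# all non-hydrogens.

# Atomic masses (u) and Bondi van der Waals radii (nm) by element.
ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  P = 30.974, ZN = 65.38)
BONDI_RADIUS <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
                  P = 0.180, ZN = 0.139)

element_lookup <- function(elements, table, what) {
  vals <- table[toupper(elements)]
  assert(!anyNA(vals), "unknown element(s) for %s lookup: %s", what,
         paste(unique(elements[is.na(vals)]), collapse = ", "))
  unname(vals)
}

#' Per-frame RMSD to a reference frame
#'
#' Each frame is least-squares superposed onto the reference frame over the
#' selected atoms (Kabsch), then the root-mean-square deviation over those
#' atoms is reported. The reference frame has RMSD 0 by construction.
#'
#' @param traj a [trajectory()].
#' @param reference_frame 1-based frame index (default 1).
#' @param selection atom indices for fit and measurement (default Calpha).
#' @return numeric vector of per-frame RMSD values (nm).
#' @export
rmsd_series <- function(traj, reference_frame = 1L, selection = NULL) {
  sel <- resolve_atom_selection(traj, selection)
  assert(length(sel) >= 3L, "RMSD needs at least 3 selected atoms")
  ref <- traj$coords[reference_frame, sel, , drop = TRUE]
  check_non_collinear(ref)
  ref0 <- sweep(ref, 2, colMeans(ref))
  vapply(seq_len(n_frames(traj)), function(f) {
    mob <- traj$coords[f, sel, , drop = TRUE]
    mob0 <- sweep(mob, 2, colMeans(mob))
    R <- kabsch_rotation(mob0, ref0)
    sqrt(mean(rowSums((mob0 %*% R - ref0)^2)))
  }, 0)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each residue's Calpha atom about its
#' time-averaged position. The trajectory should be superposed first (see
#' [superpose()]); RMSF is computed on the coordinates as given.
#'
#' @param traj a superposed [trajectory()] with at least 2 frames.
#' @param selection residue numbers to include (default: all).
#' @param state optional label ("apo"/"bound") stored with the profile.
#' @return An object of class `FlexibilityProfile`: data frame with columns
#'   `resno` and `rmsf` (nm) and attribute `state`.
#' @export
rmsf_profile <- function(traj, selection = NULL, state = NA_character_) {
  assert(n_frames(traj) >= 2L, "RMSF needs at least 2 frames")
  idx <- ca_indices(traj)
  resno <- traj$atom_meta$resno[idx]
  if (!is.null(selection)) {
    keep <- resno %in% as.integer(selection)
    idx <- idx[keep]
    resno <- resno[keep]
  }
  pos <- traj$coords[, idx, , drop = FALSE]
  mean_pos <- apply(pos, c(2, 3), mean)
  dev2 <- sweep(pos, c(2, 3), mean_pos)^2
  rmsf <- sqrt(vapply(seq_along(idx), function(a) {
    mean(rowSums(dev2[, a, , drop = FALSE][, 1, ]))
  }, 0))
  out <- data.frame(resno = resno, rmsf = rmsf)
  attr(out, "state") <- state
  class(out) <- c("FlexibilityProfile", class(out))
  out
}

#' Heavy-atom contact counts per frame
#'
#' Counts pairs of heavy atoms closer than `cutoff`, excluding pairs within
#' the same residue. A cell-list neighbor search is used; it is exact (the
#' test suite checks equality with the all-pairs count).
#'
#' @param traj a [trajectory()] with heavy-atom flags in its metadata.
#' @param cutoff contact distance in nm (default 0.45).
#' @return integer vector of per-frame contact counts.
#' @export
count_contacts <- function(traj, cutoff = 0.45) {
  heavy <- which(traj$atom_meta$heavy)
  assert(length(heavy) > 0L, "no heavy atoms in trajectory")
  resno <- traj$atom_meta$resno[heavy]
  vapply(seq_len(n_frames(traj)), function(f) {
    contact_count_frame(traj$coords[f, heavy, , drop = TRUE], resno, cutoff)
  }, 0L)
}

# Cell-list contact count for one frame.
contact_count_frame <- function(xyz, resno, cutoff) {
  n <- nrow(xyz)
  if (n < 2L) return(0L)
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cutoff)
  nc <- apply(cell, 2, max) + 1L
  key <- cell[, 1] + nc[1] * (cell[, 2] + nc[2] * cell[, 3])
  buckets <- split(seq_len(n), key)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  count <- 0L
  cut2 <- cutoff^2
  bucket_cells <- do.call(rbind, lapply(buckets, function(i) cell[i[1], ]))
  cell_of <- stats::setNames(seq_along(buckets), names(buckets))
  for (bi in seq_along(buckets)) {
    a <- buckets[[bi]]
    base <- bucket_cells[bi, ]
    for (o in seq_len(nrow(offsets))) {
      nb_cell <- base + offsets[o, ]
      if (any(nb_cell < 0) || any(nb_cell >= nc)) next
      nb_key <- as.character(nb_cell[1] + nc[1] * (nb_cell[2] + nc[2] * nb_cell[3]))
      bj <- cell_of[nb_key]
      if (is.na(bj) || bj < bi) next
      b <- buckets[[bj]]
      if (bj == bi) {
        if (length(a) < 2L) next
        pr <- utils::combn(a, 2L)
        ii <- pr[1, ]; jj <- pr[2, ]
      } else {
        g <- expand.grid(ii = a, jj = b)
        ii <- g$ii; jj <- g$jj
      }
      ok <- resno[ii] != resno[jj]
      if (!any(ok)) next
      d2 <- rowSums((xyz[ii[ok], , drop = FALSE] - xyz[jj[ok], , drop = FALSE])^2)
      count <- count + sum(d2 < cut2)
    }
  }
  count
}

# Reference O(n^2) implementation kept for oracle comparisons.
contact_count_brute <- function(xyz, resno, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  mask <- upper.tri(d) & outer(resno, resno, `!=`)
  sum(d[mask] < cutoff)
}

#' Geometric hydrogen-bond detection
#'
#' A bond is recorded when the donor-acceptor distance is below `d_cut` and
#' the donor-hydrogen-acceptor angle exceeds `angle_cut`. Donors are N/O
#' atoms with a covalently attached hydrogen (H within 0.12 nm); acceptors
#' are N/O atoms other than the donor.
#'
#' @param traj a [trajectory()] whose metadata includes hydrogens.
#' @param d_cut donor-acceptor distance cutoff in nm (default 0.35).
#' @param angle_cut donor-hydrogen-acceptor angle cutoff in degrees
#'   (default 150).
#' @return list with one data frame per frame (columns `donor`, `hydrogen`,
#'   `acceptor`, `distance`, `angle`, atom indices 1-based). When the
#'   topology contains no hydrogens an empty result is returned with a
#'   warning.
#' @export
hydrogen_bonds <- function(traj, d_cut = 0.35, angle_cut = 150) {
  meta <- traj$atom_meta
  h_idx <- which(meta$element == "H")
  no_idx <- which(meta$element %in% c("N", "O"))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0))
  if (length(h_idx) == 0L) {
    warning("no hydrogens in topology; hydrogen-bond list is empty")
    return(rep(list(empty), n_frames(traj)))
  }
  lapply(seq_len(n_frames(traj)), function(f) {
    xyz <- traj$coords[f, , , drop = TRUE]
    # covalent donor-H assignment from this frame's geometry
    dh <- expand.grid(d = no_idx, h = h_idx)
    dvec <- xyz[dh$d, , drop = FALSE] - xyz[dh$h, , drop = FALSE]
    dh <- dh[sqrt(rowSums(dvec^2)) < 0.12, , drop = FALSE]
    if (nrow(dh) == 0L) return(empty)
    rows <- lapply(seq_len(nrow(dh)), function(r) {
      don <- dh$d[r]; hyd <- dh$h[r]
      acc <- setdiff(no_idx, don)
      da <- sqrt(rowSums(sweep(xyz[acc, , drop = FALSE], 2, xyz[don, ])^2))
      keep <- da < d_cut
      if (!any(keep)) return(NULL)
      acc <- acc[keep]; da <- da[keep]
      v1 <- sweep(xyz[rep(don, length(acc)), , drop = FALSE], 2, xyz[hyd, ])
      v2 <- sweep(xyz[acc, , drop = FALSE], 2, xyz[hyd, ])
      cosang <- rowSums(v1 * v2) /
        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      ok <- ang > angle_cut
      if (!any(ok)) return(NULL)
      data.frame(donor = don, hydrogen = hyd, acceptor = acc[ok],
                 distance = da[ok], angle = ang[ok])
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) empty else out
  })
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum m_i |x_i - x_cm|^2 / sum m_i)`, mass-weighted by default
#' with masses assigned from elements.
#'
#' @param traj a [trajectory()].
#' @param mass_weighted use atomic masses (default) or unit masses.
#' @return numeric vector of per-frame Rg (nm).
#' @export
radius_of_gyration <- function(traj, mass_weighted = TRUE) {
  m <- if (mass_weighted) {
    element_lookup(traj$atom_meta$element, ELEMENT_MASS, "mass")
  } else {
    rep(1, n_atoms(traj))
  }
  assert(sum(m) > 0, "total mass must be positive")
  vapply(seq_len(n_frames(traj)), function(f) {
    xyz <- matrix(traj$coords[f, , ], ncol = 3)
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, 0)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area
#'
#' For each atom, quadrature points are placed on the sphere of radius
#' (vdW radius + probe); the accessible fraction (points not inside any
#' other atom's expanded sphere) times the sphere area gives the per-atom
#' SASA. Radii are the Bondi set, looked up by element.
#'
#' @param xyz `n x 3` coordinate matrix (nm) for one frame.
#' @param elements element symbol per atom (used for radii), or NULL when
#'   `radii` is given.
#' @param radii optional explicit per-atom radii (nm).
#' @param probe probe radius in nm (default 0.14, water).
#' @param n_sphere_points quadrature points per atom (default 960).
#' @return list with `atom_area` (nm^2 per atom) and `total` (nm^2).
#' @export
sasa <- function(xyz, elements = NULL, radii = NULL, probe = 0.14,
                 n_sphere_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (is.null(radii)) {
    assert(!is.null(elements), "provide either elements or radii")
    radii <- element_lookup(elements, BONDI_RADIUS, "radius")
  }
  assert(all(radii > 0), "radii must be positive")
  assert(probe >= 0, "probe radius must be non-negative")
  pts <- sphere_points(n_sphere_points)
  ext <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    sp <- sweep(pts * ext[i], 2, xyz[i, ], `+`)
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ext + ext[i])^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj <- rowSums(sweep(sp[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= ext[j]^2
    }
    area[i] <- 4 * pi * ext[i]^2 * mean(acc)
  }
  list(atom_area = area, total = sum(area))
}

#' Essential dynamics (PCA of Calpha fluctuations)
#'
#' Builds the 3N x 3N covariance matrix of Calpha positional fluctuations
#' over frames and diagonalizes it. Eigenvalues (variances, nm^2) are
#' sorted descending with a numerical floor at zero; projections of the
#' centered coordinates onto each eigenvector are returned.
#'
#' @param traj a superposed [trajectory()] with more than one frame.
#' @param selection residue numbers (default: all residues' Calpha atoms).
#' @return An object of class `EssentialDynamics`: list with `mean_coords`
#'   (3N vector), `eigenvalues`, `eigenvectors` (3N x 3N, columns),
#'   `projections` (frames x 3N), `residues`.
#' @export
essential_dynamics <- function(traj, selection = NULL) {
  assert(n_frames(traj) >= 2L, "essential dynamics needs at least 2 frames")
  idx <- ca_indices(traj)
  resno <- traj$atom_meta$resno[idx]
  if (!is.null(selection)) {
    keep <- resno %in% as.integer(selection)
    idx <- idx[keep]
    resno <- resno[keep]
  }
  nf <- n_frames(traj)
  X <- matrix(NA_real_, nf, 3L * length(idx))
  for (f in seq_len(nf)) {
    X[f, ] <- as.numeric(t(traj$coords[f, idx, , drop = TRUE]))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / nf  # population covariance
  es <- eigen(covm, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  structure(
    list(mean_coords = mu, eigenvalues = vals, eigenvectors = es$vectors,
         projections = Xc %*% es$vectors, residues = resno),
    class = "EssentialDynamics"
  )
}

#' @export
print.EssentialDynamics <- function(x, ...) {
  fr <- x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<EssentialDynamics> %d residues; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              length(x$residues), 100 * fr[1], 100 * fr[2]))
  invisible(x)
}

#' Boltzmann-weighted free-energy surface over PC projections
#'
#' Histograms the first two principal-component projections and converts
#' occupancies to free energies `F = -kT ln(P / P_max)`, so the most
#' populated bin has F = 0 exactly and empty bins are unbounded (Inf).
#'
#' @param projections `frames x >= 2` matrix; the first two columns are
#'   used (PC1, PC2).
#' @param bins number of bins per axis (>= 2).
#' @param temperature temperature in K (stored; energies are in kT units,
#'   multiply by 0.008314 * T for kJ/mol).
#' @return An object of class `FreeEnergySurface`: list with `pc1_edges`,
#'   `pc2_edges`, `free_energy` (bins x bins, kT), `counts`, `temperature`.
#' @export
free_energy_surface <- function(projections, bins = 32L, temperature = 300) {
  projections <- as.matrix(projections)
  assert(nrow(projections) >= 1L, "need at least one frame")
  assert(bins >= 2L, "bins must be at least 2")
  p1 <- projections[, 1]
  p2 <- projections[, 2]
  e1 <- seq(min(p1), max(p1), length.out = bins + 1L)
  e2 <- seq(min(p2), max(p2), length.out = bins + 1L)
  if (e1[1] == e1[bins + 1L]) e1 <- e1 + seq(-0.5, 0.5, length.out = bins + 1L)
  if (e2[1] == e2[bins + 1L]) e2 <- e2 + seq(-0.5, 0.5, length.out = bins + 1L)
  b1 <- pmin(pmax(findInterval(p1, e1, rightmost.closed = TRUE), 1L), bins)
  b2 <- pmin(pmax(findInterval(p2, e2, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (f in seq_along(b1)) counts[b1[f], b2[f]] <- counts[b1[f], b2[f]] + 1L
  fe <- matrix(Inf, bins, bins)
  occ <- counts > 0L
  fe[occ] <- -log(counts[occ] / max(counts))
  structure(
    list(pc1_edges = e1, pc2_edges = e2, free_energy = fe, counts = counts,
         temperature = temperature),
    class = "FreeEnergySurface"
  )
}

#' Export porcupine displacement vectors for a principal component
#'
#' Writes per-residue displacement vectors (the eigenvector slice scaled by
#' `scale`) as a PyMOL command script drawing arrows from the mean
#' structure, plus a plain-text TSV (residue, dx, dy, dz in nm).
#'
#' @param ed an [essential_dynamics()] result.
#' @param component principal component index (1-based).
#' @param scale arrow length multiplier.
#' @param out_path output script path; the TSV is written next to it with a
#'   `.tsv` extension.
#' @return list with `script` and `table` paths, invisibly.
#' @export
porcupine_export <- function(ed, component = 1L, scale = 1,
                             out_path = "porcupine.pml") {
  assert(component >= 1L && component <= ncol(ed$eigenvectors),
         "component %d out of range", component)
  vec <- matrix(ed$eigenvectors[, component], ncol = 3L, byrow = TRUE) * scale
  base <- matrix(ed$mean_coords, ncol = 3L, byrow = TRUE)
  tsv_path <- paste0(tools::file_path_sans_ext(out_path), ".tsv")
  df <- data.frame(resno = ed$residues, dx = vec[, 1], dy = vec[, 2],
                   dz = vec[, 3])
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(
    "# porcupine arrows: per-residue displacement along a principal component",
    "# units: nm (multiply by 10 for Angstrom); residue numbering 1-based",
    "from pymol.cgo import CYLINDER", "obj = []"
  )
  tip <- base + vec
  for (i in seq_len(nrow(base))) {
    lines <- c(lines, sprintf(
      "obj += [CYLINDER, %.4f,%.4f,%.4f, %.4f,%.4f,%.4f, 0.02, 1,0.5,0, 1,0.5,0]",
      base[i, 1] * 10, base[i, 2] * 10, base[i, 3] * 10,
      tip[i, 1] * 10, tip[i, 2] * 10, tip[i, 3] * 10))
  }
  lines <- c(lines, sprintf("cmd.load_cgo(obj, 'pc%d_porcupine')", component))
  writeLines(lines, out_path)
  invisible(list(script = out_path, table = tsv_path))
}
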