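#' Trajectory container
#'
#' A `Trajectory` holds Cartesian coordinates for a fixed set of atoms over
#' time together with per-atom metadata. Coordinates are stored in nanometres
#' internally; readers convert from Angstrom where the file format requires
#' (PDB, DCD). Residue numbering is 1-based throughout, following the PDB
#' convention.
#'
#' @param coords numeric array of dimension `frames x atoms x 3`, in nm.
#' @param atom_meta data frame with one row per atom and columns `elety`
#'   (atom name), `resno` (1-based residue index), `resid` (residue name),
#'   `chain` (chain id), `element` (element symbol) and `heavy` (logical,
#'   `TRUE` for non-hydrogen atoms).
#' @param times numeric vector of per-frame times in ps, strictly increasing.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(coords, atom_meta, times = NULL) {
  assert(is.array(coords) && length(dim(coords)) == 3L && dim(coords)[3] == 3L,
         "coords must be a frames x atoms x 3 array")
  assert(all(is.finite(coords)), "coordinates must be finite")
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  assert(is.data.frame(atom_meta) && nrow(atom_meta) == n_atoms,
         "atom_meta must have one row per atom (%d), got %d rows",
         n_atoms, nrow(atom_meta))
  needed <- c("elety", "resno", "resid", "chain", "element", "heavy")
  missing_cols <- setdiff(needed, names(atom_meta))
  assert(length(missing_cols) == 0L,
         "atom_meta is missing columns: %s", paste(missing_cols, collapse = ", "))
  assert(!anyNA(atom_meta$resno), "every atom must map to a residue")
  if (is.null(times)) times <- seq_len(n_frames) - 1
  assert(length(times) == n_frames, "times must have one value per frame")
  assert(n_frames < 2L || all(diff(times) > 0), "times must be strictly increasing")
  structure(
    list(coords = coords, atom_meta = atom_meta, times = as.numeric(times)),
    class = "Trajectory"
  )
}

#' @export
print.Trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<Trajectory> %d frames, %d atoms, %d residues\n",
              d[1], d[2], length(unique(x$atom_meta$resno))))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[1]
n_atoms <- function(traj) dim(traj$coords)[2]

#' Number of frames / atoms in a trajectory
#' @param traj a [trajectory()] object.
#' @return integer count.
#' @export
trajectory_frames <- function(traj) n_frames(traj)

#' @rdname trajectory_frames
#' @export
trajectory_atoms <- function(traj) n_atoms(traj)

# Indices of Calpha-like atoms (atom name "CA"); falls back to one atom per
# residue when no CA atoms exist (e.g. single-particle synthetic systems).
ca_indices <- function(traj) {
  idx <- which(traj$atom_meta$elety == "CA")
  if (length(idx) == 0L) {
    idx <- which(!duplicated(traj$atom_meta$resno))
  }
  idx[order(traj$atom_meta$resno[idx])]
}

# Per-residue Calpha coordinates for one frame (or time-averaged).
ca_coords <- function(traj, frame = NULL) {
  idx <- ca_indices(traj)
  if (is.null(frame)) {
    apply(traj$coords[, idx, , drop = FALSE], c(2, 3), mean)
  } else {
    traj$coords[frame, idx, , drop = TRUE]
  }
}

file_ext_lower <- function(path) tolower(tools::file_ext(path))

#' Read a trajectory from standard MD file formats
#'
#' Supported topology formats: PDB and GRO. Supported coordinate formats:
#' DCD (CHARMM/X-PLOR binary). When `coords_path` is `NULL` the coordinates
#' stored in the topology file are used (a single- or multi-model PDB).
#' PDB and DCD coordinates are in Angstrom and are converted to nm; GRO files
#' are already in nm.
#'
#' @param topology_path path to a PDB or GRO file.
#' @param coords_path optional path to a DCD file with the frame coordinates.
#' @param dt frame spacing in ps used to populate frame times (default 1).
#' @return A [trajectory()] object.
#' @export
load_trajectory <- function(topology_path, coords_path = NULL, dt = 1) {
  assert(file.exists(topology_path), "topology file not found: %s", topology_path)
  ext <- file_ext_lower(topology_path)
  top <- switch(ext,
    pdb = read_topology_pdb(topology_path),
    gro = read_topology_gro(topology_path),
    stopf("unsupported topology format '.%s' (supported: .pdb, .gro)", ext)
  )
  if (is.null(coords_path)) {
    coords <- top$coords
  } else {
    assert(file.exists(coords_path), "coordinate file not found: %s", coords_path)
    cext <- file_ext_lower(coords_path)
    coords <- switch(cext,
      dcd = read_coords_dcd(coords_path),
      xtc = stopf("XTC reading is not supported; supported coordinate formats: .dcd"),
      stopf("unsupported coordinate format '.%s' (supported: .dcd)", cext)
    )
    assert(dim(coords)[2] == nrow(top$atom_meta),
           "atom-count mismatch: topology has %d atoms, coordinate file has %d",
           nrow(top$atom_meta), dim(coords)[2])
  }
  trajectory(coords, top$atom_meta, times = (seq_len(dim(coords)[1]) - 1) * dt)
}

read_topology_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  elem <- atoms$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- substr(gsub("[^A-Za-z].*$", "", atoms$elety), 1, 1)
  }
  elem <- toupper(trimws(elem))
  meta <- data.frame(
    elety = trimws(atoms$elety),
    resno = as.integer(atoms$resno),
    resid = trimws(atoms$resid),
    chain = ifelse(is.na(atoms$chain), "A", atoms$chain),
    element = elem,
    heavy = elem != "H",
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(meta)
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  list(coords = coords / 10, atom_meta = meta)  # Angstrom -> nm
}

read_topology_gro <- function(path) {
  lines <- readLines(path)
  assert(length(lines) >= 3L, "malformed GRO file: %s", path)
  na <- as.integer(trimws(lines[2]))
  assert(is.finite(na) && length(lines) >= 2L + na,
         "GRO atom count (%s) does not match file length", lines[2])
  body <- lines[3:(2 + na)]
  resno <- as.integer(substr(body, 1, 5))
  resid <- trimws(substr(body, 6, 10))
  elety <- trimws(substr(body, 11, 15))
  x <- as.numeric(substr(body, 21, 28))
  y <- as.numeric(substr(body, 29, 36))
  z <- as.numeric(substr(body, 37, 44))
  elem <- toupper(substr(gsub("[^A-Za-z].*$", "", elety), 1, 1))
  meta <- data.frame(
    elety = elety, resno = resno, resid = resid, chain = "A",
    element = elem, heavy = elem != "H", stringsAsFactors = FALSE
  )
  coords <- array(NA_real_, c(1, na, 3))
  coords[1, , ] <- cbind(x, y, z)  # GRO is already in nm
  list(coords = coords, atom_meta = meta)
}

read_coords_dcd <- function(path) {
  dcd <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(dcd))) dcd <- matrix(dcd, nrow = 1)
  nf <- nrow(dcd)
  na <- ncol(dcd) / 3
  coords <- array(NA_real_, c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(dcd[f, ], ncol = 3, byrow = TRUE)
  }
  coords / 10  # Angstrom -> nm
}

#' Write a trajectory to a PDB topology plus DCD coordinates
#'
#' Writes a minimal single-chain PDB topology (first frame) and a CHARMM-style
#' binary DCD coordinate file. Coordinates are converted from the internal nm
#' representation to Angstrom, per both formats' conventions. The pair of
#' files round-trips through [load_trajectory()].
#'
#' @param traj a [trajectory()] object with at least one frame.
#' @param topology_path output PDB path.
#' @param coords_path output DCD path.
#' @return Invisibly, a list with the two paths.
#' @export
export_trajectory <- function(traj, topology_path, coords_path) {
  assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  assert(n_frames(traj) >= 1L, "cannot export a trajectory with zero frames")
  text <- file_ext_lower(topology_path)
  assert(text == "pdb", "unsupported topology format '.%s' (supported: .pdb)", text)
  cext <- file_ext_lower(coords_path)
  assert(cext == "dcd", "unsupported coordinate format '.%s' (supported: .dcd)", cext)

  meta <- traj$atom_meta
  xyz_ang <- matrix(aperm(traj$coords[1, , , drop = FALSE] * 10, c(3, 2, 1)),
                    nrow = 1)  # x1,y1,z1,x2,... in Angstrom
  bio3d::write.pdb(
    file = topology_path,
    xyz = as.numeric(t(traj$coords[1, , ] * 10)),
    resno = meta$resno, resid = meta$resid, chain = meta$chain,
    elety = meta$elety, elesy = meta$element
  )
  write_dcd(traj$coords * 10, coords_path,
            dt = if (n_frames(traj) > 1) diff(traj$times)[1] else 1)
  invisible(list(topology = topology_path, coords = coords_path))
}

# Minimal X-PLOR style DCD writer (no unit cell, 4-byte Fortran records).
# No DCD writer exists in the installed R stack; readers (bio3d::read.dcd,
# MDAnalysis) accept this layout.
write_dcd <- function(coords_ang, path, dt = 1) {
  nf <- dim(coords_ang)[1]
  na <- dim(coords_ang)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    raw_con <- rawConnection(raw(0), "wb")
    writer(raw_con)
    payload <- rawConnectionValue(raw_con)
    close(raw_con)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(as.integer(length(payload)), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- as.integer(nf)   # NSET
  icntrl[2] <- 1L               # ISTART
  icntrl[3] <- 1L               # NSAVC
  icntrl[4] <- as.integer(nf)   # total steps
  rec(function(c2) {
    writeChar("CORD", c2, nchars = 4, eos = NULL)
    writeBin(as.integer(icntrl[1:9]), c2, size = 4, endian = "little")
    # X-PLOR convention: DELTA is a 64-bit double spanning words 10-11
    writeBin(as.numeric(dt), c2, size = 8, endian = "little")
    writeBin(as.integer(icntrl[12:20]), c2, size = 4, endian = "little")
  })
  title <- sprintf("%-80s", "Created by allokit")
  rec(function(c2) {
    writeBin(1L, c2, size = 4, endian = "little")
    writeChar(title, c2, nchars = 80, eos = NULL)
  })
  rec(function(c2) writeBin(as.integer(na), c2, size = 4, endian = "little"))
  for (f in seq_len(nf)) {
    for (ax in 1:3) {
      vals <- as.numeric(coords_ang[f, , ax])
      rec(function(c2) writeBin(vals, c2, size = 4, endian = "little"))
    }
  }
  invisible(path)
}

#' Least-squares superposition onto a reference frame
#'
#' Removes global translation and rotation by rigidly fitting every frame to
#' `reference_frame` with the Kabsch algorithm, computed over a subset of
#' atoms (default: Calpha atoms) and applied to all atoms.
#'
#' @param traj a [trajectory()] object.
#' @param reference_frame 1-based frame index to fit onto (default 1).
#' @param selection integer or logical vector of atom indices used for the
#'   fit; default selects Calpha atoms.
#' @return A new, superposed [trajectory()]; the input is not modified.
#' @export
superpose <- function(traj, reference_frame = 1L, selection = NULL) {
  assert(inherits(traj, "Trajectory"), "traj must be a Trajectory")
  sel <- resolve_atom_selection(traj, selection)
  assert(length(sel) >= 3L, "superposition needs at least 3 selected atoms, got %d",
         length(sel))
  ref <- traj$coords[reference_frame, sel, , drop = TRUE]
  check_non_collinear(ref)
  ref_c <- colMeans(ref)
  ref0 <- sweep(ref, 2, ref_c)
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    mob <- traj$coords[f, sel, , drop = TRUE]
    mob_c <- colMeans(mob)
    R <- kabsch_rotation(sweep(mob, 2, mob_c), ref0)
    frame <- traj$coords[f, , , drop = TRUE]
    out[f, , ] <- sweep(sweep(frame, 2, mob_c) %*% R, 2, ref_c, `+`)
  }
  trajectory(out, traj$atom_meta, traj$times)
}

resolve_atom_selection <- function(traj, selection) {
  if (is.null(selection)) return(ca_indices(traj))
  if (is.logical(selection)) selection <- which(selection)
  selection <- as.integer(selection)
  assert(all(selection >= 1L & selection <= n_atoms(traj)),
         "atom selection out of range")
  selection
}

check_non_collinear <- function(x) {
  sv <- svd(sweep(x, 2, colMeans(x)))$d
  assert(sv[2] > 1e-10 * max(sv[1], 1e-12),
         "degenerate superposition: selected atoms are collinear")
  invisible(TRUE)
}

# Kabsch: rotation R such that mob %*% R best fits ref (both centered).
kabsch_rotation <- function(mob, ref) {
  s <- svd(t(mob) %*% ref)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Uniform temporal downsampling
#'
#' Selects `target_frames` frames at even index spacing, always keeping the
#' first frame; the i-th kept frame (0-based) is `floor(i * (N-1) / (n-1))`.
#' If the trajectory already has `target_frames` frames or fewer it is
#' returned unchanged.
#'
#' @param traj a [trajectory()] object.
#' @param target_frames desired frame count (at least 2).
#' @return A downsampled [trajectory()].
#' @export
downsample_uniform <- function(traj, target_frames) {
  assert(target_frames >= 2L, "target_frames must be at least 2")
  nf <- n_frames(traj)
  if (target_frames >= nf) return(traj)
  idx0 <- floor((seq_len(target_frames) - 1) * (nf - 1) / (target_frames - 1))
  idx <- as.integer(idx0) + 1L
  trajectory(traj$coords[idx, , , drop = FALSE], traj$atom_meta, traj$times[idx])
}
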